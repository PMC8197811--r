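#' Specification for a synthetic environment series
#'
#' Describes a fabricated residue-environment series with prescribed
#' descriptor values and barriers, used to exercise every downstream stage
#' (loading, descriptor computation, scaling fits) without external data.
#' Descriptor targets are built exactly into the generated geometries and
#' charge tables; only barriers carry noise, since the barrier is the
#' uncertain, computed quantity in a real series.
#'
#' @param targets A data.frame with columns `label`, `dcat` (Angstrom),
#'   `qcat` (e), `barrier` (kcal/mol); labels unique.
#' @param sigma Standard deviation of Gaussian barrier noise, kcal/mol
#'   (>= 0; 0 reproduces the barriers exactly).
#' @param start_charge Nucleophile group charge at the reactant complex, e.
#' @param end_charge Nucleophile group charge at the product asymptote, e
#'   (used by [charge_evolution()]).
#' @param midpoint,width Logistic midpoint and width of the charge-transfer
#'   profile along the normalized reaction coordinate.
#' @param seed Integer seed (mandatory — every stochastic draw in the
#'   generator is reproducible).
#' @return A list of class `"series_spec"`.
#' @export
series_spec <- function(targets, sigma = 0, start_charge = -0.94,
                        end_charge = -0.10, midpoint = 0.5, width = 0.1,
                        seed) {
  stopifnot(is.data.frame(targets),
            all(c("label", "dcat", "qcat", "barrier") %in% names(targets)))
  if (anyDuplicated(targets$label))
    stop("duplicate labels in series spec", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be >= 0", call. = FALSE)
  if (missing(seed) || is.na(seed))
    stop("a seed is mandatory", call. = FALSE)
  structure(list(targets = targets, sigma = sigma,
                 start_charge = start_charge, end_charge = end_charge,
                 midpoint = midpoint, width = width,
                 seed = as.integer(seed)),
            class = "series_spec")
}

#' Nucleophile group charge along the reaction coordinate
#'
#' Logistic interpolation of the nucleophile group charge from its
#' reactant-complex value to its product-asymptote value as negative charge
#' flows to the leaving group. The raw logistic is rescaled so the endpoints
#' are met exactly at `s = 0` and `s = 1`; with the default midpoint 0.5 the
#' value at the midpoint is the mean of the two endpoint charges. Monotone
#' in `s` for positive width.
#'
#' @param s Normalized arc length in \[0, 1\] (vectorized).
#' @param start,end Group charge at `s = 0` and `s = 1`, e.
#' @param midpoint Logistic midpoint in (0, 1).
#' @param width Logistic width (> 0).
#' @return Group charge(s) in e.
#' @export
charge_evolution <- function(s, start = -0.94, end = -0.10,
                             midpoint = 0.5, width = 0.1) {
  if (any(s < 0 | s > 1))
    stop("arc length s must lie in [0, 1]", call. = FALSE)
  stopifnot(width > 0)
  L <- function(u) 1 / (1 + exp(-(u - midpoint) / width))
  frac <- (L(s) - L(0)) / (L(1) - L(0))
  start + (end - start) * frac
}

# Collinear O-C-Cl placement with prescribed forming/leaving distances.
collinear_geometry <- function(df, dl, comment = "") {
  geometry(c("O", "C", "Cl"),
           rbind(c(0, 0, 0),
                 c(0, 0, df),
                 c(0, 0, df + dl)),
           comment = comment)
}

# Charge table over the 3-atom construct; atom 1 (the nucleophile pseudo
# group) carries exactly the requested group charge, the rest balance to a
# net charge of -1.
synthetic_charges <- function(nucleophile_charge) {
  q1 <- nucleophile_charge
  q2 <- 0.40
  charge_table(1:3, c("Nu", "C1", "Cl1"), c(q1, q2, -1 - q1 - q2))
}

#' Generate one synthetic reaction record
#'
#' Builds minimal collinear three-atom (O, C, Cl) stationary-point
#' geometries and RC/TS charge tables such that the two descriptors come
#' out exactly at their targets: the TS forming O1--C1 distance is fixed at
#' the 2.0 Angstrom base value and the leaving C1--Cl1 distance at
#' `2.0 + target_dcat`; the RC nucleophile group charge is `start_charge`
#' and the TS group charge `start_charge + target_qcat`. No chemical realism
#' beyond the two distances and the group charges is attempted — downstream
#' code reads nothing else.
#'
#' @param label Environment label.
#' @param target_dcat Target distance descriptor, Angstrom
#'   (> -1.8 so the leaving bond stays positive).
#' @param target_qcat Target charge-transfer descriptor, e.
#' @param barrier Barrier in kcal/mol.
#' @param start_charge RC nucleophile group charge, e.
#' @return A `"reaction_record"` with
#'   `compute_dcat(record) == target_dcat` and
#'   `compute_qcat(record) == target_qcat` exactly.
#' @export
generate_record <- function(label, target_dcat, target_qcat, barrier,
                            start_charge = -0.94) {
  stopifnot(is.finite(target_dcat), is.finite(target_qcat))
  if (target_dcat <= -1.8)
    stop("target_dcat <= -1.8 would collapse the leaving bond",
         call. = FALSE)
  ts <- stationary_point(
    "TS", collinear_geometry(2.0, 2.0 + target_dcat),
    charges = synthetic_charges(start_charge + target_qcat))
  rc <- stationary_point(
    "RC", collinear_geometry(3.0, 1.8),
    charges = synthetic_charges(start_charge))
  pc <- stationary_point("PC", collinear_geometry(1.43, 3.2))
  reaction_record(label, rc = rc, ts = ts, pc = pc,
                  leaving_bond = c(2L, 3L), forming_bond = c(1L, 2L),
                  nucleophile = 1L, barrier = barrier)
}

#' Generate a synthetic environment series with files on disk
#'
#' Writes XYZ geometries, charge CSVs and a ready-to-load `series.yaml`
#' under `outdir`, then loads the result back through [load_series()] so the
#' returned object is guaranteed loadable. Barriers are the spec's targets
#' plus `Normal(0, sigma)` noise drawn under the spec's seed; with
#' `sigma = 0` and a fixed spec the emitted files are byte-identical across
#' runs.
#'
#' @param spec A `"series_spec"`.
#' @param outdir Output directory (created if needed).
#' @return The loaded `"environment_series"`, with the config path in
#'   attribute `"config"`.
#' @export
generate_series <- function(spec, outdir) {
  stopifnot(inherits(spec, "series_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  tg <- spec$targets
  noise <- stats::rnorm(nrow(tg), 0, spec$sigma)
  envs <- vector("list", nrow(tg))
  for (i in seq_len(nrow(tg))) {
    rec <- generate_record(tg$label[i], tg$dcat[i], tg$qcat[i],
                           tg$barrier[i] + noise[i],
                           start_charge = spec$start_charge)
    stem <- paste0("env_", gsub("[^A-Za-z0-9_-]", "_", tg$label[i]))
    paths <- list(rc_xyz = paste0(stem, "_rc.xyz"),
                  ts_xyz = paste0(stem, "_ts.xyz"),
                  pc_xyz = paste0(stem, "_pc.xyz"),
                  rc_charges = paste0(stem, "_rc_charges.csv"),
                  ts_charges = paste0(stem, "_ts_charges.csv"))
    write_xyz(rec$points$RC$geometry, file.path(outdir, paths$rc_xyz))
    write_xyz(rec$points$TS$geometry, file.path(outdir, paths$ts_xyz))
    write_xyz(rec$points$PC$geometry, file.path(outdir, paths$pc_xyz))
    write_charge_table(rec$points$RC$charges,
                       file.path(outdir, paths$rc_charges))
    write_charge_table(rec$points$TS$charges,
                       file.path(outdir, paths$ts_charges))
    envs[[i]] <- c(list(label = as.character(tg$label[i])), paths,
                   list(c1 = 2L, cl1 = 3L, o1 = 1L,
                        nucleophile_indices = list(1L),
                        barrier_kcal_mol = rec$barrier))
  }
  cfg <- file.path(outdir, "series.yaml")
  yaml::write_yaml(list(barrier_kind = "free_energy", environments = envs),
                   cfg, precision = 15L)
  out <- load_series(cfg)
  attr(out, "config") <- cfg
  out
}

#' Assemble a synthetic series in memory
#'
#' Like [generate_series()] but without touching the filesystem — useful for
#' simulation studies with many replicates.
#'
#' @param spec A `"series_spec"`.
#' @return An `"environment_series"`.
#' @export
generate_series_in_memory <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  set.seed(spec$seed)
  tg <- spec$targets
  noise <- stats::rnorm(nrow(tg), 0, spec$sigma)
  records <- lapply(seq_len(nrow(tg)), function(i)
    generate_record(tg$label[i], tg$dcat[i], tg$qcat[i],
                    tg$barrier[i] + noise[i],
                    start_charge = spec$start_charge))
  environment_series(records)
}
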