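#' Construct a stationary point
#'
#' One of the three stationary points along an SN2 reaction path: reactant
#' complex (RC), transition state (TS) or product complex (PC). The geometry
#' is mandatory; the charge table and energy are optional at construction
#' time (descriptor computations that need them fail late with a precise
#' message).
#'
#' @param role One of `"RC"`, `"TS"`, `"PC"`.
#' @param geometry An `"xyz_geometry"`, or `NULL` for a charges-only point
#'   (a stationary point whose geometry is not available but whose group
#'   charges are).
#' @param charges Optional `"charge_table"`.
#' @param energy Optional energy in kcal/mol.
#' @return An object of class `"stationary_point"`.
#' @export
stationary_point <- function(role, geometry = NULL, charges = NULL,
                             energy = NULL) {
  role <- as.character(role)[1L]
  if (!role %in% c("RC", "TS", "PC"))
    stop("role must be one of 'RC', 'TS', 'PC'; got '", role, "'",
         call. = FALSE)
  if (is.null(geometry) && is.null(charges))
    stop("a stationary point needs a geometry, a charge table, or both",
         call. = FALSE)
  if (!is.null(geometry)) stopifnot(inherits(geometry, "xyz_geometry"))
  if (!is.null(charges)) stopifnot(inherits(charges, "charge_table"))
  if (!is.null(energy)) {
    energy <- as.numeric(energy)[1L]
    if (!is.finite(energy)) stop("energy must be finite", call. = FALSE)
  }
  structure(list(role = role, geometry = geometry, charges = charges,
                 energy = energy),
            class = "stationary_point")
}

#' Construct a reaction record for one environment
#'
#' Bundles the RC/TS/PC stationary points of one active-site environment with
#' the atom selections that define the SN2 step: the breaking bond between
#' the central carbon (C1) and the leaving chloride (Cl1), the forming bond
#' between the nucleophile oxygen (O1) and C1, and the full nucleophile atom
#' selection over which group charges are summed.
#'
#' @param label Environment name, e.g. `"3"`, `"water"`.
#' @param rc,ts,pc `"stationary_point"` objects with matching roles (`pc`
#'   optional — descriptors only read RC and TS).
#' @param leaving_bond Integer pair `c(C1, Cl1)` of 1-based atom indices.
#' @param forming_bond Integer pair `c(O1, C1)`; must share exactly the C1
#'   index with `leaving_bond`.
#' @param nucleophile Integer vector of nucleophile atom indices; non-empty
#'   and excluding Cl1.
#' @param barrier Activation barrier in kcal/mol, `NA` if unknown.
#' @param barrier_kind `"free_energy"` (default) or `"potential_energy"`.
#' @return An object of class `"reaction_record"`.
#' @export
reaction_record <- function(label, rc = NULL, ts = NULL, pc = NULL,
                            leaving_bond, forming_bond, nucleophile,
                            barrier = NA_real_,
                            barrier_kind = c("free_energy",
                                             "potential_energy")) {
  label <- as.character(label)[1L]
  if (!nzchar(label)) stop("record label must be non-empty", call. = FALSE)
  barrier_kind <- match.arg(barrier_kind)
  leaving_bond <- as.integer(leaving_bond)
  forming_bond <- as.integer(forming_bond)
  nucleophile <- as.integer(nucleophile)
  if (length(leaving_bond) != 2L || length(forming_bond) != 2L)
    stop("leaving_bond and forming_bond must each be an index pair",
         call. = FALSE)
  shared <- intersect(leaving_bond, forming_bond)
  if (length(shared) != 1L)
    stop("record '", label, "': leaving and forming bonds must share ",
         "exactly one atom (the central carbon C1); they share ",
         length(shared), call. = FALSE)
  cl1 <- setdiff(leaving_bond, shared)
  if (length(nucleophile) < 1L)
    stop("record '", label, "': nucleophile selection is empty",
         call. = FALSE)
  if (cl1 %in% nucleophile)
    stop("record '", label, "': nucleophile selection must not contain ",
         "the leaving-group atom (index ", cl1, ")", call. = FALSE)
  for (pt in list(rc, ts, pc)) {
    if (!is.null(pt)) stopifnot(inherits(pt, "stationary_point"))
  }
  barrier <- as.numeric(barrier)[1L]
  if (!is.na(barrier) && !is.finite(barrier))
    stop("record '", label, "': barrier must be finite or NA", call. = FALSE)
  structure(
    list(label = label,
         points = list(RC = rc, TS = ts, PC = pc),
         leaving_bond = leaving_bond,
         forming_bond = forming_bond,
         nucleophile = nucleophile,
         barrier = barrier,
         barrier_kind = barrier_kind),
    class = "reaction_record"
  )
}

#' Assemble an environment series
#'
#' @param records List of `"reaction_record"` objects with unique labels.
#' @return An object of class `"environment_series"`; `[[` and `$records`
#'   give access to individual records.
#' @export
environment_series <- function(records) {
  if (!is.list(records) || length(records) < 1L)
    stop("a series needs at least one record", call. = FALSE)
  ok <- vapply(records, inherits, logical(1L), what = "reaction_record")
  if (!all(ok))
    stop("all series entries must be reaction_record objects", call. = FALSE)
  labels <- vapply(records, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    stop("duplicate environment labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  names(records) <- labels
  structure(list(records = records), class = "environment_series")
}

#' @export
print.environment_series <- function(x, ...) {
  cat(sprintf("<environment_series: %d environments>\n", length(x$records)))
  for (r in x$records)
    cat(sprintf("  %-8s barrier = %s kcal/mol (%s)\n", r$label,
                ifelse(is.na(r$barrier), "NA", format(r$barrier)),
                r$barrier_kind))
  invisible(x)
}

#' @export
length.environment_series <- function(x) length(x$records)

#' @export
`[[.environment_series` <- function(x, i) x$records[[i]]

# Resolve a possibly-relative path against the config file's directory.
resolve_path <- function(p, base) {
  if (is.null(p) || is.na(p)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

#' Load an environment series from a config file
#'
#' The config (YAML or JSON, decided by file extension) holds a list
#' `environments:`; each entry has keys `label`, `rc_xyz`, `ts_xyz`,
#' `pc_xyz` (optional), `rc_charges`, `ts_charges` (optional), `c1`, `cl1`,
#' `o1`, `nucleophile_indices`, `barrier_kcal_mol`, and optionally
#' `role: predict` to hold the environment out of fitting. A top-level
#' `barrier_kind: potential_energy` switches all barriers from the default
#' free-energy interpretation. File paths are resolved relative to the
#' config file.
#'
#' Every geometry is loaded and every atom selection is validated against it
#' before the series is returned.
#'
#' @param config Path to a YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return An `"environment_series"`. Records gain a logical
#'   `predict_only` field reflecting `role: predict`.
#' @export
load_series <- function(config) {
  if (!file.exists(config))
    stop("series config not found: ", config, call. = FALSE)
  ext <- tolower(tools::file_ext(config))
  cfg <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(config),
    "json" = jsonlite::fromJSON(config, simplifyDataFrame = FALSE),
    stop("unrecognised config extension '.", ext,
         "' (need .yaml, .yml or .json)", call. = FALSE))
  envs <- cfg$environments
  if (is.null(envs) || length(envs) < 1L)
    stop("config '", config, "' lists no environments", call. = FALSE)
  base <- dirname(normalizePath(config))
  kind <- cfg$barrier_kind %||% "free_energy"
  records <- lapply(envs, function(e) {
    need <- c("label", "c1", "cl1", "o1", "nucleophile_indices")
    missing <- setdiff(need, names(e))
    if (length(missing))
      stop("environment entry missing keys: ",
           paste(missing, collapse = ", "), call. = FALSE)
    load_point <- function(role, xyz_key, chg_key) {
      p <- resolve_path(e[[xyz_key]], base)
      ch <- NULL
      cp <- resolve_path(e[[chg_key]], base)
      if (!is.null(cp)) {
        if (!file.exists(cp))
          stop("environment '", e$label, "': missing file ", cp,
               call. = FALSE)
        ch <- read_charge_table(cp)
      }
      if (is.null(p) && is.null(ch)) return(NULL)
      g <- NULL
      if (!is.null(p)) {
        if (!file.exists(p))
          stop("environment '", e$label, "': missing file ", p,
               call. = FALSE)
        g <- read_xyz(p)
      }
      stationary_point(role, geometry = g, charges = ch)
    }
    rc <- load_point("RC", "rc_xyz", "rc_charges")
    ts <- load_point("TS", "ts_xyz", "ts_charges")
    pc <- load_point("PC", "pc_xyz", "pc_charges")
    sel <- as.integer(unlist(e$nucleophile_indices))
    idx <- c(e$c1, e$cl1, e$o1, sel)
    with_geom <- Filter(function(pt) !is.null(pt) && !is.null(pt$geometry),
                        list(rc, ts, pc))
    for (pt in with_geom) {
      if (any(idx > n_atoms(pt$geometry)) || any(idx < 1L))
        stop("environment '", e$label, "': atom selection out of range ",
             "for ", pt$role, " geometry (", n_atoms(pt$geometry),
             " atoms)", call. = FALSE)
    }
    rec <- reaction_record(
      label = e$label, rc = rc, ts = ts, pc = pc,
      leaving_bond = c(e$c1, e$cl1),
      forming_bond = c(e$o1, e$c1),
      nucleophile = sel,
      barrier = e$barrier_kcal_mol %||% NA_real_,
      barrier_kind = kind)
    rec$predict_only <- identical(e$role, "predict")
    rec
  })
  environment_series(records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
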