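#' Distance-difference reactivity descriptor
#'
#' For an SN2 step, the descriptor is the length of the breaking bond minus
#' the length of the forming bond, both measured at the transition state:
#' \deqn{D_{cat} = d_l - d_f}
#' where \eqn{d_l} is the C1--Cl1 distance to the leaving group and
#' \eqn{d_f} the O1--C1 distance to the incoming nucleophile. A larger value
#' marks a "later", more product-like transition state — faster bond
#' breaking/formation and hence a lower activation barrier.
#'
#' @param record A `"reaction_record"` with a TS geometry.
#' @return The descriptor in Angstrom.
#' @export
compute_dcat <- function(record) {
  stopifnot(inherits(record, "reaction_record"))
  ts <- record$points$TS
  if (is.null(ts) || is.null(ts$geometry))
    stop("record '", record$label, "': no TS geometry; the distance ",
         "descriptor is a transition-state quantity", call. = FALSE)
  g <- ts$geometry
  dl <- bond_length(g, record$leaving_bond[1L], record$leaving_bond[2L])
  df <- bond_length(g, record$forming_bond[1L], record$forming_bond[2L])
  dl - df
}

#' Charge-transfer reactivity descriptor
#'
#' The nucleophile group charge (sum of signed atomic charges over the
#' nucleophile selection) at the transition state minus at the reactant
#' complex:
#' \deqn{Q_{cat} = q_{TS} - q_{RC}}
#' A larger value means more negative charge has already flowed from the
#' nucleophile toward the leaving group by the transition state — faster
#' charge transfer and higher reactivity.
#'
#' @param record A `"reaction_record"` whose RC and TS both carry charge
#'   tables covering the nucleophile selection.
#' @return The descriptor in units of e.
#' @export
compute_qcat <- function(record) {
  stopifnot(inherits(record, "reaction_record"))
  for (role in c("RC", "TS")) {
    pt <- record$points[[role]]
    if (is.null(pt))
      stop("record '", record$label, "': no ", role, " stationary point; ",
           "the charge-transfer descriptor needs both RC and TS",
           call. = FALSE)
    if (is.null(pt$charges))
      stop("record '", record$label, "': ", role, " has no charge table; ",
           "the charge-transfer descriptor needs charges at both RC and TS",
           call. = FALSE)
  }
  qts <- group_charge(record$points$TS$charges, record$nucleophile)
  qrc <- group_charge(record$points$RC$charges, record$nucleophile)
  qts - qrc
}

#' Descriptor table for an environment series
#'
#' Computes both descriptors for every record that can supply them. A record
#' without a TS geometry yields `NA` for the distance descriptor; a record
#' missing RC or TS charges yields `NA` for the charge-transfer descriptor.
#' A record providing neither is an error (it contributes nothing to any
#' scaling fit).
#'
#' @param series An `"environment_series"` with at least one record.
#' @return A data.frame of class `"descriptor_table"` with columns `label`,
#'   `dcat` (Angstrom), `qcat` (e), `barrier` (kcal/mol), `predict_only`,
#'   in series order.
#' @export
descriptor_table <- function(series) {
  stopifnot(inherits(series, "environment_series"))
  if (length(series$records) < 1L)
    stop("descriptor_table needs at least 1 record", call. = FALSE)
  rows <- lapply(series$records, function(r) {
    dcat <- tryCatch(compute_dcat(r), error = function(e) NA_real_)
    qcat <- tryCatch(compute_qcat(r), error = function(e) NA_real_)
    if (is.na(dcat) && is.na(qcat))
      stop("record '", r$label, "': neither descriptor is computable ",
           "(no TS geometry and no RC/TS charges)", call. = FALSE)
    data.frame(label = r$label, dcat = dcat, qcat = qcat,
               barrier = r$barrier,
               predict_only = isTRUE(r$predict_only),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("descriptor_table", "data.frame")
  out
}

#' Write a descriptor table as TSV
#'
#' Columns `label, dcat_angstrom, qcat_e, barrier_kcal_mol`. Descriptors are
#' computed at full precision internally; this report layer rounds to two
#' decimals, matching how such values are conventionally tabulated.
#'
#' @param tab A `"descriptor_table"`.
#' @param path Output TSV path.
#' @param digits Decimal places for the report (default 2).
#' @return Invisibly, `path`.
#' @export
write_descriptor_table <- function(tab, path, digits = 2L) {
  stopifnot(inherits(tab, "descriptor_table"))
  out <- data.frame(label = tab$label,
                    dcat_angstrom = round(tab$dcat, digits),
                    qcat_e = round(tab$qcat, digits),
                    barrier_kcal_mol = round(tab$barrier, digits))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Reactivity ordering by a descriptor
#'
#' Sorts environments by descending descriptor value and checks the
#' monotonicity that a valid reactivity descriptor must show: the activation
#' barrier strictly increases as the descriptor decreases. Ties in the
#' descriptor are reported, not silently ordered.
#'
#' @param rows A `"descriptor_table"` (or compatible data.frame) with at
#'   least two rows carrying the chosen descriptor.
#' @param descriptor `"dcat"` or `"qcat"`.
#' @return A list of class `"reactivity_order"` with elements `labels`
#'   (descending descriptor), `descriptor`, `values`, `barriers`,
#'   `monotone` (TRUE iff barriers strictly increase down the ordering) and
#'   `ties` (labels involved in tied descriptor values, if any).
#' @export
reactivity_order <- function(rows, descriptor = c("qcat", "dcat")) {
  descriptor <- match.arg(descriptor)
  x <- rows[[descriptor]]
  keep <- !is.na(x)
  if (sum(keep) < 2L)
    stop("need at least 2 rows with a '", descriptor, "' value",
         call. = FALSE)
  lab <- rows$label[keep]; x <- x[keep]; b <- rows$barrier[keep]
  ord <- order(x, decreasing = TRUE)
  x <- x[ord]; lab <- lab[ord]; b <- b[ord]
  tied <- duplicated(x) | duplicated(x, fromLast = TRUE)
  ties <- if (any(tied)) lab[tied] else character(0L)
  if (length(ties))
    warning("tied descriptor values among environments: ",
            paste(ties, collapse = ", "), call. = FALSE)
  monotone <- !anyNA(b) && length(ties) == 0L && all(diff(b) > 0)
  structure(list(labels = lab, descriptor = descriptor, values = x,
                 barriers = b, monotone = monotone, ties = ties),
            class = "reactivity_order")
}

#' @export
print.reactivity_order <- function(x, ...) {
  cat(sprintf("%s ordering: %s\n", x$descriptor,
              paste(x$labels, collapse = " > ")))
  cat(sprintf("barrier rises as descriptor falls: %s\n",
              ifelse(x$monotone, "yes", "no")))
  if (length(x$ties))
    cat("ties:", paste(x$ties, collapse = ", "), "\n")
  invisible(x)
}
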