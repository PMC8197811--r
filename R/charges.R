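#' Construct an atomic partial-charge table
#'
#' Charges are signed atomic (or group) partial charges in units of the
#' elementary charge e, keyed by 1-based atom index. The population-analysis
#' scheme that produced them is deliberately not interpreted: charges are
#' taken as given, and the scheme name is carried as metadata only. A grouped
#' row (a whole-fragment charge such as the acetate group) is representable as
#' a single pseudo-atom entry.
#'
#' @param index Integer vector of 1-based atom indices (unique).
#' @param label Character vector of atom/group labels (e.g. "O1", "Cl1").
#' @param charge Numeric vector of signed charges, e.
#' @param scheme Optional name of the population analysis (metadata only).
#' @return A data.frame of class `"charge_table"` with columns
#'   `index`, `label`, `charge`.
#' @export
charge_table <- function(index, label, charge, scheme = NA_character_) {
  index <- as.integer(index)
  charge <- as.numeric(charge)
  if (length(index) < 1L)
    stop("charge table has no rows", call. = FALSE)
  if (anyNA(index) || any(index < 1L))
    stop("charge indices must be positive integers", call. = FALSE)
  if (anyDuplicated(index))
    stop("duplicate atom index in charge table: ",
         paste(unique(index[duplicated(index)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(charge)))
    stop("charges must be finite", call. = FALSE)
  out <- data.frame(index = index, label = as.character(label),
                    charge = charge, stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  class(out) <- c("charge_table", "data.frame")
  out
}

#' Read a charge table from CSV
#'
#' Expects a UTF-8 CSV with mandatory header `index,label,charge` and one row
#' per atom (or per pseudo-atom group).
#'
#' @param path Path to the CSV file.
#' @return A `"charge_table"`.
#' @export
read_charge_table <- function(path) {
  if (!file.exists(path))
    stop("charge table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character", "character"))
  required <- c("index", "label", "charge")
  if (!all(required %in% names(df)))
    stop("charge CSV '", path, "' must have header 'index,label,charge'",
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("charge CSV '", path, "' has no rows", call. = FALSE)
  q <- suppressWarnings(as.numeric(df$charge))
  if (anyNA(q))
    stop("non-numeric charge in '", path, "' (row ",
         which(is.na(q))[1L], ")", call. = FALSE)
  charge_table(df$index, df$label, q)
}

#' Write a charge table to CSV
#' @param ct A `"charge_table"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_charge_table <- function(ct, path) {
  stopifnot(inherits(ct, "charge_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("index,label,charge",
               sprintf("%d,%s,%s", ct$index, ct$label,
                       formatC(ct$charge, format = "g", digits = 15))),
             con = con, sep = "\n")
  invisible(path)
}

#' Sum of signed charges over an atom selection
#'
#' The group charge of a fragment is the arithmetic sum of the signed atomic
#' charges of its atoms — this is how the nucleophile charge entering the
#' charge-transfer descriptor is defined.
#'
#' @param ct A `"charge_table"`.
#' @param selection Integer vector of 1-based atom indices, all present in
#'   the table.
#' @return Group charge in e.
#' @export
group_charge <- function(ct, selection) {
  stopifnot(inherits(ct, "charge_table"))
  selection <- as.integer(selection)
  if (length(selection) < 1L)
    stop("empty atom selection", call. = FALSE)
  pos <- match(selection, ct$index)
  if (anyNA(pos))
    stop("atom index absent from charge table: ",
         paste(selection[is.na(pos)], collapse = ", "), call. = FALSE)
  sum(ct$charge[pos])
}
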