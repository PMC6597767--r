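#' Per-patient kinetic parameters
#'
#' Container for the four constants of the FT4 kinetic model: the synthesis
#' rate `a` (day^-1), the decay rate `c` (l pmol^-1 day^-1), the dose giving
#' half-maximal synthesis inhibition `ic50` (mg), and the integration
#' constant `c1` (l pmol^-1), which must be strictly negative for FT4 to
#' decline under treatment.
#'
#' Published per-patient formulas are often reported through the products
#' `a*ic50` and `a*ic50*c1` rather than `a` and `c1` themselves; the
#' constructor accepts either parametrization and reconciles them.
#'
#' @param a Synthesis rate, day^-1 (positive). May be omitted when
#'   `a_ic50` is given.
#' @param c Decay rate, l pmol^-1 day^-1 (positive).
#' @param ic50 Half-maximal inhibitory dose, mg; must lie in `(0, ic50_max]`.
#' @param c1 Integration constant, l pmol^-1 (strictly negative). May be
#'   omitted when `a_ic50_c1` is given.
#' @param a_ic50 Optional product `a * ic50` (the numerator constant of the
#'   reported FT4 formulas).
#' @param a_ic50_c1 Optional product `a * ic50 * c1`.
#' @param ic50_max Upper bound for `ic50`, mg. Default 150, the accepted
#'   prescription limit.
#' @param strict_margin Margin `eps` used to enforce the strict sign
#'   constraint `c1 <= -eps`. Default `1e-8`.
#' @return An object of class `atd_params`: a list with elements
#'   `a`, `c`, `ic50`, `c1`, `strict_margin`.
#' @examples
#' # patient with reported products a*ic50 = 3.024, a*ic50*c1 = -0.154
#' p <- atd_params(a_ic50 = 3.024, c = 0.003, a_ic50_c1 = -0.154,
#'                 ic50 = 58.151)
#' p$a          # 0.052
#' initial_ft4(p)
#' @export
atd_params <- function(a = NULL, c = NULL, ic50 = NULL, c1 = NULL,
                       a_ic50 = NULL, a_ic50_c1 = NULL,
                       ic50_max = 150, strict_margin = 1e-8) {
  if (is.null(ic50) || is.null(c))
    stop("`ic50` and `c` are always required", call. = FALSE)
  if (is.null(a)) {
    if (is.null(a_ic50))
      stop("supply either `a` or the product `a_ic50`", call. = FALSE)
    a <- a_ic50 / ic50
  }
  if (is.null(c1)) {
    if (is.null(a_ic50_c1))
      stop("supply either `c1` or the product `a_ic50_c1`", call. = FALSE)
    c1 <- a_ic50_c1 / (a * ic50)
  }
  stopifnot(is.numeric(a), is.numeric(c), is.numeric(ic50), is.numeric(c1),
            length(a) == 1L, length(c) == 1L, length(ic50) == 1L,
            length(c1) == 1L)
  if (!is.finite(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  if (!is.finite(c) || c <= 0) stop("`c` must be positive", call. = FALSE)
  if (!is.finite(ic50) || ic50 <= 0 || ic50 > ic50_max)
    stop(sprintf("`ic50` must lie in (0, %g]", ic50_max), call. = FALSE)
  if (!is.finite(c1) || c1 > -strict_margin)
    stop(sprintf("`c1` must be negative (<= -%g)", strict_margin),
         call. = FALSE)
  structure(list(a = a, c = c, ic50 = ic50, c1 = c1,
                 strict_margin = strict_margin),
            class = "atd_params")
}

#' @export
print.atd_params <- function(x, ...) {
  cat("FT4 kinetic parameters\n")
  cat(sprintf("  a (synthesis rate)  : %.6g /day\n", x$a))
  cat(sprintf("  c (decay rate)      : %.6g l/pmol/day\n", x$c))
  cat(sprintf("  ic50                : %.6g mg\n", x$ic50))
  cat(sprintf("  c1                  : %.6g l/pmol\n", x$c1))
  cat(sprintf("  a*ic50 = %.4g, a*ic50*c1 = %.4g\n",
              x$a * x$ic50, x$a * x$ic50 * x$c1))
  cat(sprintf("  initial FT4 y(0,0)  : %.2f pmol/l\n", initial_ft4(x)))
  invisible(x)
}

#' Serialize parameters to a JSON document
#'
#' Writes a flat key-value JSON document with keys `a`, `c`, `ic50`, `c1`
#' plus optional provenance metadata (patient id, fit date, objective).
#'
#' @param p An [atd_params] object.
#' @param path Output file path.
#' @param meta Optional named list of provenance fields
#'   (e.g. `patient_id`, `objective`, `fit_date`).
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path, meta = list()) {
  stopifnot(inherits(p, "atd_params"))
  doc <- c(list(a = p$a, c = p$c, ic50 = p$ic50, c1 = p$c1), meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter document written by [write_params()]
#'
#' @param path JSON file path.
#' @return A list with element `params` (an [atd_params]) and `meta`
#'   (any extra fields found in the document).
#' @export
read_params <- function(path) {
  doc <- jsonlite::fromJSON(path)
  need <- c("a", "c", "ic50", "c1")
  if (!all(need %in% names(doc)))
    stop("parameter document must contain keys a, c, ic50, c1",
         call. = FALSE)
  p <- atd_params(a = doc$a, c = doc$c, ic50 = doc$ic50, c1 = doc$c1)
  list(params = p, meta = doc[setdiff(names(doc), need)])
}
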