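#' Canonical identifier of a drug combination
#'
#' Combinations are plain character vectors of drug identifiers. The canonical
#' id is order-independent: members are de-duplicated and sorted
#' lexicographically (C locale) before being joined with `";"`, so the same
#' drug set always maps to the same id.
#'
#' @param drugs character vector of drug identifiers (length >= 1).
#' @return a single string, e.g. `"d1;d3"`.
#' @examples
#' comboId(c("gemcitabine", "docetaxel"))
#' comboId(c("docetaxel", "gemcitabine"))  # identical
#' @export
comboId <- function(drugs) {
  drugs <- as.character(drugs)
  if (length(drugs) < 1L || any(is.na(drugs)) || any(!nzchar(drugs)))
    stop("a combination needs at least one non-empty drug id")
  paste(sort(unique(drugs), method = "radix"), collapse = ";")
}

#' @rdname comboId
#' @return `comboMembers()` returns the sorted, de-duplicated member vector.
#' @export
comboMembers <- function(drugs) {
  sort(unique(as.character(drugs)), method = "radix")
}

## Concentration unit handling: everything is converted through micromolar.
.conc_units <- c(M = 1e6, mM = 1e3, uM = 1, nM = 1e-3, pM = 1e-6)

#' Convert concentrations between molar units
#'
#' @param x numeric vector of concentrations.
#' @param from,to unit names among `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`
#'   (case-sensitive; `"µM"` is accepted as an alias of `"uM"`).
#' @return numeric vector in the target unit.
#' @examples
#' convertConc(10, "nM", "uM")  # 0.01
#' @export
convertConc <- function(x, from, to = "uM") {
  norm <- function(u) {
    u <- gsub("µ", "u", as.character(u))
    bad <- !(u %in% names(.conc_units))
    if (any(bad)) stop("unknown concentration unit: ", paste(unique(u[bad]), collapse = ", "))
    u
  }
  from <- norm(from); to <- norm(to)
  unname(x * .conc_units[from] / .conc_units[to[1L]])
}

## Roman-numeral display labels for ratio settings and combination groups.
.roman <- function(i) as.character(utils::as.roman(i))

## Clip values into an open interval; used before logit transforms.
.clip01 <- function(x, lo = 0.005, hi = 0.995) pmin(pmax(x, lo), hi)

## Run an expression with a temporary RNG seed, restoring global state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

## stopifnot-style scalar checks with readable messages
.check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single finite number")
  if (x < lower || x > upper)
    stop("'", name, "' must be in [", lower, ", ", upper, "]")
  if (integer && x != round(x))
    stop("'", name, "' must be an integer")
  invisible(TRUE)
}
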