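#' Cell-state composition of a compartment
#'
#' A point on the 3-simplex giving the proportions of normal, defective and
#' cancerous cells in one compartment of an organism. The germline role holds
#' PGC/APSC proportions; the somatic role holds somatic-cell proportions.
#' Mature organisms of every lineage are described by one composition per
#' role.
#'
#' Inputs whose components sum to 1 within `1e-9` are renormalized exactly to
#' the simplex; larger deviations are treated as construction errors rather
#' than silently absorbed.
#'
#' @param p numeric vector of length 3: proportions of normal, defective and
#'   cancerous cells, each in `[0, 1]`, summing to 1.
#' @param role `"germline"` or `"somatic"`.
#' @return A `cell_composition`: a named numeric vector of length 3
#'   (`normal`, `defective`, `cancerous`) with a `role` attribute.
#' @examples
#' cell_composition(c(0.9, 0.08, 0.02))
#' cell_composition(c(0, 1, 0), role = "somatic")
#' @export
cell_composition <- function(p, role = c("germline", "somatic")) {
  role <- match.arg(role)
  p <- as.numeric(p)
  if (length(p) != 3L || anyNA(p)) {
    stop("a cell composition needs 3 finite proportions", call. = FALSE)
  }
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(s, digits = 12), ")",
         call. = FALSE)
  }
  p <- pmin(pmax(p / s, 0), 1)
  structure(c(normal = p[[1L]], defective = p[[2L]], cancerous = p[[3L]]),
            role = role, class = "cell_composition")
}

#' @export
print.cell_composition <- function(x, ...) {
  cat(sprintf("<cell_composition: %s>\n", attr(x, "role")))
  print(unclass(x)[1:3], ...)
  invisible(x)
}

is_composition <- function(x) inherits(x, "cell_composition")

## Coerce 3-vectors on the simplex without demanding the class; internal
## plumbing so that plain numeric triples work at every operation boundary.
as_composition <- function(x, role = "germline") {
  if (is_composition(x)) return(x)
  cell_composition(x, role = role)
}
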