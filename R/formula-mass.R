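# Monoisotopic masses (u) of the elements occurring in the default library.
.MONO_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, P = 30.97376151, S = 31.97207069)

.PROTON_MASS <- 1.007276467

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Character formula such as \code{"C9H11NO2"} (elements
#'   C, H, N, O, P, S).
#' @return Monoisotopic neutral mass in u.
#' @examples
#' monoisotopicMass("C9H11NO2") # L-phenylalanine, 165.0790
#' @export
monoisotopicMass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!length(parts) || paste(parts, collapse = "") != f)
      stop("cannot parse formula: ", f, call. = FALSE)
    total <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      n <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.MONO_MASS))
        stop("unknown element '", el, "' in formula ", f, call. = FALSE)
      total <- total + .MONO_MASS[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Theoretical m/z of a singly charged adduct
#'
#' \code{[M+H]+} adds and \code{[M-H]-} subtracts one proton mass.
#'
#' @param mass Neutral monoisotopic mass in u.
#' @param polarity \code{"pos"} or \code{"neg"}.
#' @return m/z in Thomsons.
#' @export
adductMz <- function(mass, polarity = c("pos", "neg")) {
  polarity <- match.arg(polarity)
  if (polarity == "pos") mass + .PROTON_MASS else mass - .PROTON_MASS
}
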