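# Habitat-suitability index from categorical land cover: binary
# classification at fine resolution, then block aggregation to a 0-100
# count per landscape cell.

#' Classify a land-cover grid into binary habitat
#'
#' @param landcover Integer matrix of land-cover class codes (fine
#'   resolution, e.g. 100 m).
#' @param preferred Vector of class codes considered habitat.
#' @param known_classes Optional vector of all valid codes; codes outside
#'   it raise a warning and are treated as non-habitat.
#' @return Integer 0/1 matrix of the same shape.
#' @export
classify_landcover <- function(landcover, preferred, known_classes = NULL) {
  if (!is.null(known_classes)) {
    bad <- setdiff(unique(as.vector(landcover)), known_classes)
    if (length(bad)) {
      warning("unknown land-cover code(s) treated as non-habitat: ",
              paste(bad, collapse = ", "))
    }
  }
  out <- matrix(as.integer(landcover %in% preferred),
                nrow(landcover), ncol(landcover))
  out
}

#' Aggregate binary habitat to the suitability index
#'
#' Counts habitat cells in each `factor x factor` block, giving an
#' integer suitability index in \[0, factor^2\] (0-100 for the default
#' factor 10, i.e. 100 m cells inside 1 km cells). If the fine grid's
#' dimensions are not divisible by `factor` it is zero-padded at the
#' bottom/right edge, with a message.
#'
#' @param binary Integer 0/1 matrix (fine resolution).
#' @param factor Aggregation factor (default 10).
#' @return Integer matrix of block counts (a `HabitatMap`).
#' @export
aggregate_suitability <- function(binary, factor = 10L) {
  factor <- as.integer(factor)
  if (any(!binary %in% c(0L, 1L))) stop("binary grid must contain only 0/1")
  nr <- nrow(binary)
  nc <- ncol(binary)
  if (nr %% factor || nc %% factor) {
    message("padding fine grid with zeros to a multiple of ", factor)
    nr2 <- ceiling(nr / factor) * factor
    nc2 <- ceiling(nc / factor) * factor
    pad <- matrix(0L, nr2, nc2)
    pad[seq_len(nr), seq_len(nc)] <- binary
    binary <- pad
    nr <- nr2
    nc <- nc2
  }
  nrc <- nr %/% factor
  ncc <- nc %/% factor
  out <- matrix(0L, nrc, ncc)
  ri <- (seq_len(nr) - 1L) %/% factor + 1L
  ci <- (seq_len(nc) - 1L) %/% factor + 1L
  agg <- rowsum(binary, ri)            # sum fine rows into coarse rows
  agg <- t(rowsum(t(agg), ci))         # then fine cols into coarse cols
  storage.mode(agg) <- "integer"
  matrix(agg, nrc, ncc)
}

#' Mark a boundary buffer on a habitat map
#'
#' Buffer cells stay in-domain for the dynamics (individuals may live and
#' disperse there) but are excluded from likelihood aggregation and
#' evaluation; this mirrors retaining a border strip around the study
#' area to soften edge effects.
#'
#' @param habitat Suitability matrix.
#' @param width Buffer ring width in cells.
#' @return Logical matrix, `TRUE` for core (non-buffer) cells.
#' @export
buffer_mask <- function(habitat, width = 0L) {
  nr <- nrow(habitat)
  nc <- ncol(habitat)
  m <- matrix(FALSE, nr, nc)
  if (2 * width >= nr || 2 * width >= nc)
    stop("buffer width leaves no core cells")
  m[(width + 1):(nr - width), (width + 1):(nc - width)] <- TRUE
  m
}
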