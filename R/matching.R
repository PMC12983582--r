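#' Leadfield with lobe labels
#'
#' A sources x channels gain matrix with a cortical-lobe label per source.
#' The matrix can come from any forward model; the synthetic module can
#' emit one from its ground-truth mixing matrix via [leadfield_from_truth()].
#'
#' @param G Numeric sources x channels matrix with nonzero rows.
#' @param labels Character vector of per-source lobe names (one of
#'   `occipital`, `temporal`, `sensorimotor`, `parietal`, `frontal`,
#'   `other`).
#' @param positions Optional sources x 3 coordinate matrix.
#' @return An object of class `leadfield`.
#' @export
leadfield <- function(G, labels, positions = NULL) {
  G <- as.matrix(G)
  if (any(sqrt(rowSums(G^2)) == 0)) abort("Leadfield rows must be nonzero.")
  labels <- as.character(labels)
  if (length(labels) != nrow(G)) abort("One lobe label per leadfield row is required.")
  known <- c("occipital", "temporal", "sensorimotor", "parietal", "frontal", "other")
  if (!all(labels %in% known)) {
    abort(sprintf("Unknown lobe label(s): %s",
                  paste(setdiff(labels, known), collapse = ", ")))
  }
  structure(list(G = G, labels = labels, positions = positions),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sources x %d channels\n", nrow(x$G), ncol(x$G)))
  print(table(x$labels))
  invisible(x)
}

#' Read a leadfield from a delimited matrix plus label CSV
#'
#' @param matrix_path TSV file holding the sources x channels gain matrix.
#' @param labels_path CSV file with a `lobe` column (one row per source).
#' @return A [leadfield()].
#' @export
read_leadfield <- function(matrix_path, labels_path) {
  G <- unname(as.matrix(utils::read.table(matrix_path, sep = "\t", header = FALSE)))
  lab <- utils::read.csv(labels_path)
  if (!"lobe" %in% names(lab)) abort("Labels CSV must contain a `lobe` column.")
  leadfield(G, lab$lobe)
}

#' Build a leadfield from simulation ground truth
#'
#' @param truth A `sim_truth` from [make_recording()].
#' @param labels Lobe labels, one per simulated source.
#' @return A [leadfield()].
#' @export
leadfield_from_truth <- function(truth, labels = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  n_src <- nrow(truth$mixing)
  if (is.null(labels)) {
    labels <- rep(c("parietal", "sensorimotor", "occipital", "temporal"),
                  length.out = n_src)
  }
  leadfield(truth$mixing, labels)
}

#' Absolute cosine distance between two vectors
#'
#' \eqn{d = 1 - |a \cdot b| / (\lVert a\rVert \lVert b\rVert)}. The absolute
#' value makes the distance invariant to the sign (and any nonzero
#' rescaling) of either vector, as befits spatial patterns that are defined
#' only up to polarity.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return A distance in `[0, 1]`; 0 for (anti)parallel vectors, 1 for
#'   orthogonal ones.
#' @export
#' @examples
#' cosine_distance(c(1, 2), c(-1, -2))  # 0
cosine_distance <- function(a, b) {
  if (length(a) != length(b)) abort("Vectors must have equal length.")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("Cosine distance is undefined for a zero vector.")
  d <- 1 - abs(sum(a * b)) / (na * nb)
  min(max(d, 0), 1)
}

#' Match a spatial pattern to a leadfield source
#'
#' Computes the absolute cosine distance between the pattern and every
#' leadfield row, takes the argmin (ties broken deterministically by lowest
#' source index), and accepts the match iff the minimum distance is strictly
#' below `threshold`. The matched source's lobe label is attached; rejected
#' matches carry `NA` as lobe.
#'
#' @param pattern Numeric pattern vector (length = leadfield channels).
#' @param lf A [leadfield()].
#' @param threshold Acceptance threshold on the distance.
#' @param component Identifier carried through to the result.
#' @return A one-row tibble: `component`, `source`, `distance`, `lobe`,
#'   `accepted`.
#' @export
match_component <- function(pattern, lf, threshold = 0.15, component = 1L) {
  stopifnot(inherits(lf, "leadfield"))
  if (length(pattern) != ncol(lf$G)) {
    abort("Pattern length must equal the number of leadfield channels.")
  }
  d <- vapply(seq_len(nrow(lf$G)),
              function(i) cosine_distance(pattern, lf$G[i, ]), numeric(1))
  best <- which.min(d)  # which.min returns the first (lowest) index on ties
  accepted <- d[best] < threshold
  tibble(
    component = component,
    source = as.integer(best),
    distance = d[best],
    lobe = if (accepted) lf$labels[best] else NA_character_,
    accepted = accepted
  )
}

#' Match all SSD patterns against a leadfield
#'
#' @param ssd An `ssd_model` (its pattern columns are matched) or a
#'   channels x components pattern matrix.
#' @param lf A [leadfield()].
#' @param threshold Acceptance threshold on the absolute cosine distance.
#' @param components Which pattern columns to match; default all.
#' @return A tibble with one row per component, as [match_component()].
#' @export
match_components <- function(ssd, lf, threshold = 0.15, components = NULL) {
  A <- if (inherits(ssd, "ssd_model")) ssd$patterns else as.matrix(ssd)
  components <- components %||% seq_len(ncol(A))
  purrr::map_dfr(components, function(i) {
    match_component(A[, i], lf, threshold = threshold, component = i)
  })
}
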