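#' Cross-tabulate two clusterings
#'
#' Builds the contingency table between a predicted clustering and a
#' reference labeling over the intersection of their spot universes.
#' Spots present in only one labeling are dropped (their number is
#' reported in the `n_dropped` attribute). A display matrix
#' `log10(n + 1)` is attached for heatmap plotting.
#'
#' @param pred,ref named vectors or factors: spot id -> cluster label
#' @return integer matrix (predicted clusters x reference classes) of
#'   class `contingency_table`, with attributes `display` and `n_dropped`
#' @export
contingency <- function(pred, ref) {
  pred <- as_labeling(pred, "pred")
  ref <- as_labeling(ref, "ref")
  shared <- intersect(names(pred), names(ref))
  if (!length(shared)) stop("labelings share no spots")
  n_dropped <- length(union(names(pred), names(ref))) - length(shared)
  tab <- table(pred = pred[shared], ref = ref[shared])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  structure(m, display = log10(m + 1), n_dropped = n_dropped,
            class = c("contingency_table", class(m)))
}

as_labeling <- function(x, what) {
  x <- stats::setNames(as.character(x), names(x))
  if (is.null(names(x)) || anyNA(names(x))) {
    stop(what, " must be a named vector (spot id -> label)")
  }
  if (anyDuplicated(names(x))) stop("duplicate spot ids in ", what)
  x
}

# Mean over rows of the entropy of the column distribution within each row
# (natural log, 0 ln 0 := 0).
mean_row_entropy <- function(m) {
  rs <- rowSums(m)
  ent <- vapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ] / rs[i]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mean(ent)
}

#' Entropy of cluster accuracy (ECA)
#'
#' Average, over predicted clusters, of the entropy of the reference-class
#' composition within each cluster (natural log). Zero iff every predicted
#' cluster is pure — contains spots of a single reference class; the upper
#' bound is `log(N)` for `N` reference classes. Low ECA means the
#' evaluated clustering does not mix reference classes.
#'
#' @param pred,ref named label vectors (spot id -> label), or a
#'   precomputed `contingency_table` passed as `pred`
#' @return ECA value in `[0, log(N)]`
#' @export
eca <- function(pred, ref = NULL) {
  m <- if (inherits(pred, "contingency_table")) pred else contingency(pred, ref)
  mean_row_entropy(unclass(m))
}

#' Entropy of cluster purity (ECP)
#'
#' Average, over reference classes, of the entropy of the predicted-cluster
#' composition within each class (natural log). Zero iff every reference
#' class is contained in a single predicted cluster; the upper bound is
#' `log(M)` for `M` predicted clusters. Low ECP means reference classes
#' are not split apart.
#'
#' @inheritParams eca
#' @return ECP value in `[0, log(M)]`
#' @export
ecp <- function(pred, ref = NULL) {
  m <- if (inherits(pred, "contingency_table")) pred else contingency(pred, ref)
  mean_row_entropy(t(unclass(m)))
}

#' ECA/ECP of downsampled clusterings against the full-data reference
#'
#' The clustering obtained from the full data serves as the reference;
#' each downsampled clustering (one per read proportion) is evaluated
#' against it, yielding one (ECA, ECP) pair per proportion.
#'
#' @param full_labels named label vector from the full data
#' @param downsampled_labels named list: proportion (as character or
#'   numeric names) -> named label vector
#' @return data.frame `proportion, eca, ecp`
#' @export
downsample_concordance <- function(full_labels, downsampled_labels) {
  stopifnot(is.list(downsampled_labels), length(downsampled_labels) >= 1)
  props <- names(downsampled_labels)
  if (is.null(props)) stop("downsampled_labels must be named by proportion")
  rows <- lapply(seq_along(downsampled_labels), function(i) {
    m <- contingency(downsampled_labels[[i]], full_labels)
    data.frame(proportion = as.numeric(props[i]), eca = eca(m), ecp = ecp(m))
  })
  do.call(rbind, rows)
}
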