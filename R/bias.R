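#' Pairwise gene-capture-bias comparison between two platforms
#'
#' Flags genes captured strongly by one platform and poorly by another:
#' total counts at or above the `high_q` quantile in platform A and at or
#' below the `low_q` quantile in platform B (type-7 quantiles over each
#' platform's totals for the shared gene set). Two presets mirror common
#' choices — a stringent 99th/10th percentile rule and a looser 90th/10th
#' rule; both thresholds are free parameters.
#'
#' @param totals_a,totals_b named numeric vectors of per-gene total UMI
#'   counts; the comparison runs over their shared gene names (>= 10)
#' @param high_q upper quantile applied to platform A (default 0.99)
#' @param low_q lower quantile applied to platform B (default 0.10)
#' @param symmetric if TRUE, also flags genes high in B and low in A
#' @return list with `flagged` (character vector), `table` (per-gene
#'   data.frame `gene, total_a, total_b, flag_a_high, flag_b_high`) and
#'   the quantile cutoffs used
#' @export
pairwise_gene_compare <- function(totals_a, totals_b, high_q = 0.99,
                                  low_q = 0.10, symmetric = FALSE) {
  shared <- intersect(names(totals_a), names(totals_b))
  if (length(shared) < 10) {
    stop("need >= 10 shared genes for stable quantiles (got ",
         length(shared), ")")
  }
  if (high_q <= low_q) stop("high_q must exceed low_q")
  a <- totals_a[shared]; b <- totals_b[shared]
  hi_a <- stats::quantile(a, high_q, type = 7, names = FALSE)
  lo_b <- stats::quantile(b, low_q, type = 7, names = FALSE)
  flag_a <- a >= hi_a & b <= lo_b
  flag_b <- rep(FALSE, length(shared))
  if (symmetric) {
    hi_b <- stats::quantile(b, high_q, type = 7, names = FALSE)
    lo_a <- stats::quantile(a, low_q, type = 7, names = FALSE)
    flag_b <- b >= hi_b & a <= lo_a
  }
  tab <- data.frame(gene = shared, total_a = as.numeric(a),
                    total_b = as.numeric(b), flag_a_high = unname(flag_a),
                    flag_b_high = unname(flag_b), stringsAsFactors = FALSE)
  list(flagged = shared[flag_a | flag_b], table = tab,
       cutoff_high_a = hi_a, cutoff_low_b = lo_b)
}

#' Flag bias genes of a focal platform against the rest
#'
#' Candidate genes are those whose totals exceed the per-platform 90th
#' percentile in every non-focal platform — i.e. genes robustly captured
#' everywhere else. Candidates with a focal-platform total below
#' `low_cut` are the bias genes (platform-specific capture failures); the
#' remaining candidates form the comparison group for attribute analyses.
#'
#' @param totals named list of named per-gene total vectors, one per
#'   platform, sharing a gene namespace
#' @param focal_platform name of the platform under scrutiny
#' @param expressed_q quantile defining "well captured" in non-focal
#'   platforms (default 0.90, type 7, strict >)
#' @param low_cut absolute focal-total threshold below which a candidate
#'   is a bias gene (default 30; depth-dependent, so exposed)
#' @return list with `bias` and `comparison` gene vectors (a partition of
#'   the candidate set)
#' @export
flag_bias_genes <- function(totals, focal_platform, expressed_q = 0.90,
                            low_cut = 30) {
  if (!is.list(totals) || length(totals) < 2) stop("need >= 2 platforms")
  if (!focal_platform %in% names(totals)) {
    stop("focal platform '", focal_platform, "' absent")
  }
  others <- totals[setdiff(names(totals), focal_platform)]
  shared <- Reduce(intersect, lapply(totals, names))
  candidate <- rep(TRUE, length(shared))
  for (tot in others) {
    thr <- stats::quantile(tot[shared], expressed_q, type = 7, names = FALSE)
    candidate <- candidate & tot[shared] > thr
  }
  cand <- shared[candidate]
  focal <- totals[[focal_platform]][cand]
  list(bias = cand[focal < low_cut], comparison = cand[focal >= low_cut])
}

#' One-way ANOVA of a gene attribute between bias and comparison genes
#'
#' Tests whether an annotation attribute (GC fraction or gene length)
#' differs between the bias and comparison gene groups, via the standard
#' one-way ANOVA F test.
#'
#' @param bias_genes,comparison_genes character vectors (each >= 2 genes
#'   with annotation)
#' @param annotation a [gene_annotation()] data.frame
#' @param attribute `"gc_fraction"` or `"length_bp"`
#' @return list `F, df1, df2, p`
#' @export
attribute_anova <- function(bias_genes, comparison_genes, annotation,
                            attribute = c("gc_fraction", "length_bp")) {
  attribute <- match.arg(attribute)
  stopifnot(inherits(annotation, "gene_annotation"))
  val <- stats::setNames(annotation[[attribute]], annotation$gene)
  x <- val[intersect(bias_genes, names(val))]
  y <- val[intersect(comparison_genes, names(val))]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs >= 2 annotated genes")
  }
  dat <- data.frame(value = c(x, y),
                    group = factor(rep(c("bias", "comparison"),
                                       c(length(x), length(y)))))
  fit <- stats::anova(stats::lm(value ~ group, data = dat))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1])
}

#' Biotype composition of a gene set
#'
#' Frequency table of annotation biotypes among (typically bias) genes,
#' sorted descending; genes missing from the annotation are tallied as
#' `"unannotated"`.
#'
#' @param genes character vector
#' @param annotation a [gene_annotation()] data.frame
#' @return named integer vector of biotype counts
#' @export
biotype_summary <- function(genes, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (!length(genes)) return(stats::setNames(integer(0), character(0)))
  bt <- annotation$biotype[match(genes, annotation$gene)]
  bt[is.na(bt)] <- "unannotated"
  tab <- sort(table(bt), decreasing = TRUE)
  stats::setNames(as.integer(tab), names(tab))
}

#' Fraction of spots expressing a gene
#'
#' The ambient-contamination metric: the fraction of spots with at least
#' one count of the gene (e.g. a hemoglobin gene reports how widely blood
#' contamination has spread over the array).
#'
#' @param ds a `spatial_counts` object
#' @param gene gene id present in `ds`
#' @return fraction in [0, 1]
#' @export
contamination_fraction <- function(ds, gene) {
  stopifnot(inherits(ds, "spatial_counts"))
  if (!gene %in% colnames(ds$counts)) stop("unknown gene: ", gene)
  mean(ds$counts[, gene] > 0)
}
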