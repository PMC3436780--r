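# Phenotype association of metaproteins, membership/intensity and
# PTM-motif enrichment tests.

#' One-way ANOVA association of metaprotein scores with a phenotype
#'
#' Tests every metaprotein's posterior-mean factor scores against a binary
#' phenotype by one-way ANOVA, with Bonferroni adjustment across the K
#' tested factors (family level 0.05 by default).
#'
#' @param Lambda Matrix of factor scores (samples x factors, e.g.
#'   \code{fit$Lambda_mean}) or an \code{mp_fit} (scores and phenotype are
#'   then taken from the fit).
#' @param phenotype Binary labels, one per sample.
#' @param level Family-wise significance level.
#' @return A tibble with \code{metaprotein}, \code{statistic} (F),
#'   \code{p_value}, \code{p_adjusted} (Bonferroni) and \code{significant}.
#' @export
anova_association <- function(Lambda, phenotype = NULL, level = 0.05) {
  if (inherits(Lambda, "mp_fit")) {
    if (is.null(phenotype)) phenotype <- Lambda$samples$phenotype
    Lambda <- Lambda$Lambda_mean
  }
  Lambda <- as.matrix(Lambda)
  ok <- !is.na(phenotype)
  Lambda <- Lambda[ok, , drop = FALSE]
  phenotype <- factor(phenotype[ok])
  if (nlevels(phenotype) < 2) {
    stop("phenotype has a single class; ANOVA needs both", call. = FALSE)
  }
  res <- purrr::map_dfr(seq_len(ncol(Lambda)), function(k) {
    a <- stats::anova(stats::lm(Lambda[, k] ~ phenotype))
    tibble::tibble(
      metaprotein = colnames(Lambda)[k] %||% as.character(k),
      statistic = a[["F value"]][1],
      p_value = a[["Pr(>F)"]][1])
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "bonferroni")
  res$significant <- res$p_adjusted < level
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kruskal-Wallis test of membership vs. mean intensity
#'
#' For each protein with at least two identified isotope groups spread over
#' at least two metaproteins, tests whether MAP membership is associated
#' with mean observed intensity -- the "are the non-conforming peptides
#' just the dim ones?" check.  Proteins whose groups all sit in one factor
#' are reported as not applicable.
#'
#' @param fit An [run_mcmc()] fit.
#' @param ids Identification tibble.
#' @param x The (log-scale) [mp_intensity] the model was fit to.
#' @return A tibble with \code{protein_accession}, \code{n_groups},
#'   \code{n_factors}, \code{statistic} (H), \code{p_value} and
#'   \code{applicable}.
#' @export
kruskal_membership_intensity <- function(fit, ids, x) {
  memb <- dominant_membership_raw(fit, ids)
  obs <- !x$missing
  row_mean <- rowSums(x$values * obs, na.rm = TRUE) / pmax(rowSums(obs), 1L)
  memb$mean_intensity <- row_mean[memb$isotope_group_id]
  dplyr::summarise(
    dplyr::group_by(memb, .data$protein_accession),
    n_groups = dplyr::n(),
    n_factors = dplyr::n_distinct(.data$map_factor),
    statistic = if (n_groups >= 2 && n_factors >= 2) {
      unname(stats::kruskal.test(.data$mean_intensity,
                                 factor(.data$map_factor))$statistic)
    } else NA_real_,
    p_value = if (n_groups >= 2 && n_factors >= 2) {
      stats::kruskal.test(.data$mean_intensity,
                          factor(.data$map_factor))$p.value
    } else NA_real_,
    applicable = n_groups >= 2 && n_factors >= 2,
    .groups = "drop")
}

mp_motifs <- c("Q", "N", "S", "T", "P", "H", "NxS", "NxT")

motif_regex <- function(motif, sequon_strict = FALSE) {
  single <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (motif %in% single) return(motif)
  if (motif %in% c("NxS", "NxT")) {
    mid <- if (sequon_strict) "[^P]" else "."
    return(paste0("N", mid, substr(motif, 3, 3)))
  }
  stop("unsupported motif: ", motif,
       " (single residues or NxS/NxT)", call. = FALSE)
}

#' PTM-motif enrichment outside dominant metaproteins
#'
#' Builds the 2x2 table of (peptide contains motif) x (isotope group
#' outside its protein's dominant metaprotein) over identified peptides of
#' proteins that have a dominant metaprotein, and reports the sample
#' cross-product odds ratio with a two-sided Fisher exact p-value.
#' Supported motifs: any single residue (Q and N are deamidation sites, S
#' and T O-glycosylation/phosphorylation sites, P and H negative controls)
#' and the N-linked glycosylation sequons \code{NxS} / \code{NxT} (x = any
#' residue, or x != P with \code{sequon_strict}).
#'
#' @param fit An [run_mcmc()] fit.
#' @param ids Identification tibble with peptide sequences.
#' @param motif Motif descriptor.
#' @param sequon_strict Require x != P in NxS/NxT.
#' @return A list of class \code{mp_motif_enrichment}: \code{motif},
#'   \code{table} (2x2: motif yes/no x outside/inside dominant),
#'   \code{odds_ratio} and \code{p_value}.
#' @export
motif_enrichment <- function(fit, ids, motif, sequon_strict = FALSE) {
  rx <- motif_regex(motif, sequon_strict)
  memb <- dominant_membership(fit, ids)
  if (nrow(memb) == 0) stop("no protein has a dominant metaprotein", call. = FALSE)
  has_motif <- grepl(rx, memb$peptide_sequence)
  outside <- !memb$in_dominant
  tab <- matrix(c(sum(has_motif & outside), sum(has_motif & !outside),
                  sum(!has_motif & outside), sum(!has_motif & !outside)),
                2, 2, byrow = TRUE,
                dimnames = list(motif = c("yes", "no"),
                                dominant = c("outside", "inside")))
  structure(
    list(motif = motif, table = tab,
         odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
         p_value = stats::fisher.test(tab)$p.value),
    class = "mp_motif_enrichment")
}

#' @export
print.mp_motif_enrichment <- function(x, ...) {
  cat(sprintf("<mp_motif_enrichment> %s: odds ratio %.3g, Fisher p = %.3g\n",
              x$motif, x$odds_ratio, x$p_value))
  print(x$table)
  invisible(x)
}

#' @export
as_tibble.mp_motif_enrichment <- function(x, ...) {
  tibble::tibble(motif = x$motif,
                 n_motif_outside = x$table[1, 1],
                 n_motif_inside = x$table[1, 2],
                 n_other_outside = x$table[2, 1],
                 n_other_inside = x$table[2, 2],
                 odds_ratio = x$odds_ratio, p_value = x$p_value)
}
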