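# Protein-level quantitation baselines and dominant-metaprotein
# bookkeeping.

#' Protein quantitation by summation
#'
#' The simplest protein-level baseline: the per-sample sum of raw-scale
#' intensities over all identified isotope groups of a protein (missing
#' cells contribute 0).  Log-scale input is exponentiated back to counts
#' before summing; set \code{log_result = TRUE} to re-log the sums for
#' comparison with log-scale factor scores.
#'
#' @param x An [mp_intensity].
#' @param ids Identification tibble.
#' @param protein Protein accession.
#' @param log_result Re-log the summed intensities.
#' @return A list of class \code{mp_protein_expression} with
#'   \code{protein_accession}, \code{method}, \code{values} (named
#'   N-vector), \code{contributing_groups}, \code{flag}.
#' @export
protein_summation <- function(x, ids, protein, log_result = FALSE) {
  groups <- protein_groups(x, ids, protein)
  raw <- raw_scale_values(x)[groups, , drop = FALSE]
  raw[is.na(raw)] <- 0
  vals <- colSums(raw)
  if (log_result) vals <- log(pmax(vals, .Machine$double.xmin))
  new_protein_expression(protein, "summation", vals, groups)
}

#' Protein quantitation by Top-3
#'
#' Ranks a protein's identified isotope groups by mean intensity across
#' samples and returns the per-sample mean of the top three.  Ties at rank
#' three break by input row order (stable).  Proteins with fewer than three
#' groups degrade to the mean of all available groups and are flagged.
#'
#' @inheritParams protein_summation
#' @return An \code{mp_protein_expression}; \code{flag} is
#'   \code{"fewer_than_3_groups"} when the fallback applied.
#' @export
protein_top3 <- function(x, ids, protein) {
  groups <- protein_groups(x, ids, protein)
  vals <- x$values[groups, , drop = FALSE]
  obs <- !x$missing[groups, , drop = FALSE]
  row_mean <- rowSums(vals * obs, na.rm = TRUE) / pmax(rowSums(obs), 1L)
  ord <- order(-row_mean)  # stable: ties keep input row order
  top <- groups[ord[seq_len(min(3L, length(groups)))]]
  v <- x$values[top, , drop = FALSE]
  o <- !x$missing[top, , drop = FALSE]
  v[!o] <- 0
  denom <- colSums(o)
  out <- ifelse(denom > 0, colSums(v) / denom, NA_real_)
  names(out) <- colnames(x$values)
  new_protein_expression(protein, "top3", out, top,
                         flag = if (length(groups) < 3) "fewer_than_3_groups")
}

protein_groups <- function(x, ids, protein) {
  ids <- validate_identifications(ids)
  if (!protein %in% ids$protein_accession[ids$identified]) {
    stop("unknown protein: ", protein, call. = FALSE)
  }
  groups <- ids$isotope_group_id[ids$identified &
                                   ids$protein_accession == protein]
  groups <- groups[groups %in% rownames(x$values)]
  if (length(groups) == 0) {
    stop("protein ", protein, " has no isotope groups in the matrix",
         call. = FALSE)
  }
  groups
}

raw_scale_values <- function(x) {
  if (x$raw) return(x$values)
  base <- if (is.finite(x$log_base)) x$log_base else exp(1)
  base^x$values
}

new_protein_expression <- function(protein, method, values, groups,
                                   flag = NULL) {
  structure(
    list(protein_accession = protein, method = method, values = values,
         contributing_groups = groups, flag = flag),
    class = "mp_protein_expression")
}

#' @export
print.mp_protein_expression <- function(x, ...) {
  cat(sprintf("<mp_protein_expression> %s by %s over %d group(s)%s\n",
              x$protein_accession, x$method, length(x$contributing_groups),
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' @export
as_tibble.mp_protein_expression <- function(x, ...) {
  tibble::tibble(protein_accession = x$protein_accession, method = x$method,
                 sample_id = names(x$values), expression = unname(x$values))
}

#' Metaprotein expression: a posterior-mean factor score column
#'
#' @param fit An [run_mcmc()] fit.
#' @param k Factor index (1..K) or factor column label.
#' @return An \code{mp_protein_expression} holding the posterior-mean
#'   factor scores and the MAP member list; factors with no MAP members are
#'   returned with an \code{"empty_factor"} flag and a warning.
#' @export
metaprotein_expression <- function(fit, k) {
  stopifnot(inherits(fit, "mp_fit"))
  K <- ncol(fit$Lambda_mean)
  if (is.character(k)) k <- match(k, colnames(fit$Lambda_mean))
  if (is.na(k) || k < 1 || k > K) {
    stop("factor index out of range 1..", K, call. = FALSE)
  }
  members <- names(fit$map_assignment)[fit$map_assignment == k]
  flag <- NULL
  if (length(members) == 0) {
    warning("metaprotein ", colnames(fit$Lambda_mean)[k], " has no MAP members")
    flag <- "empty_factor"
  }
  out <- new_protein_expression(colnames(fit$Lambda_mean)[k], "metaprotein",
                                fit$Lambda_mean[, k], members, flag = flag)
  out
}

#' Dominant metaproteins per protein
#'
#' A protein's dominant metaprotein is the factor holding a strict majority
#' (more than half) of its identified isotope groups under the MAP
#' assignment; a protein whose groups are split without a strict majority
#' has none.
#'
#' @param fit An [run_mcmc()] fit.
#' @param ids Identification tibble.
#' @return A tibble with one row per protein: \code{protein_accession},
#'   \code{n_groups}, \code{dominant_metaprotein} (\code{NA} when none
#'   qualifies), \code{n_in_dominant} (count in the modal factor) and
#'   \code{fraction_in_dominant}.
#' @export
dominant_metaproteins <- function(fit, ids) {
  memb <- dominant_membership_raw(fit, ids)
  dplyr::summarise(
    dplyr::group_by(memb, .data$protein_accession),
    n_groups = dplyr::n(),
    n_in_dominant = max(table(.data$map_factor)),
    dominant_metaprotein = {
      tab <- table(.data$map_factor)
      top <- names(tab)[which.max(tab)]
      if (max(tab) * 2 > sum(tab)) top else NA_character_
    },
    fraction_in_dominant = n_in_dominant / n_groups,
    .groups = "drop")
}

# per identified isotope group: MAP factor label (internal building block)
dominant_membership_raw <- function(fit, ids) {
  ids <- validate_identifications(ids)
  idd <- ids[ids$identified &
               ids$isotope_group_id %in% names(fit$map_assignment), ,
             drop = FALSE]
  fl <- colnames(fit$membership_freq)
  tibble::tibble(
    isotope_group_id = idd$isotope_group_id,
    peptide_sequence = idd$peptide_sequence,
    protein_accession = idd$protein_accession,
    map_factor = fl[fit$map_assignment[idd$isotope_group_id]])
}

#' Per-peptide dominant-metaprotein membership
#'
#' For every identified isotope group of a protein that has a dominant
#' metaprotein, reports whether the group follows it -- the unit of
#' analysis for the PTM-motif enrichment tests.
#'
#' @inheritParams dominant_metaproteins
#' @return A tibble with \code{isotope_group_id}, \code{peptide_sequence},
#'   \code{protein_accession}, \code{map_factor}, \code{dominant_metaprotein}
#'   and \code{in_dominant}; proteins lacking a dominant metaprotein are
#'   excluded.
#' @export
dominant_membership <- function(fit, ids) {
  dom <- dominant_metaproteins(fit, ids)
  memb <- dominant_membership_raw(fit, ids)
  out <- dplyr::inner_join(
    memb,
    dom[!is.na(dom$dominant_metaprotein),
        c("protein_accession", "dominant_metaprotein")],
    by = "protein_accession")
  dplyr::mutate(out, in_dominant = .data$map_factor == .data$dominant_metaprotein)
}

#' Expected number of misidentifications
#'
#' Under a peptide false-identification rate \code{error_rate}, the
#' expected count of wrong identifications among \code{n_identified}
#' identified isotope groups, rounded to the nearest integer.
#'
#' @param n_identified Number of identified isotope groups.
#' @param error_rate Probability that an identification is wrong.
#' @return An integer count.
#' @export
expected_misidentifications <- function(n_identified, error_rate) {
  stopifnot(n_identified >= 0, error_rate >= 0, error_rate <= 1)
  as.integer(round(n_identified * error_rate))
}
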