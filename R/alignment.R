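# Cross-dataset feature alignment: a measured feature's retention time and
# mass-to-charge ratio in a second experiment is modeled as Gaussian around a
# per-dimension shift-and-scale transform of its coordinates in the first,
# with an unknown 2x2 residual covariance.  Matching is greedy best-first
# under a one-to-one constraint, with a posterior-odds stopping rule against
# a uniform background density.

#' Read feature coordinates (retention time, m/z)
#'
#' @param path TSV/CSV with columns \code{feature_id}, \code{rt_min}
#'   (retention time, minutes) and \code{mz} (mass-to-charge, Thomson).
#' @return A tibble with columns \code{feature_id}, \code{rt}, \code{mz}.
#' @export
read_feature_coordinates <- function(path) {
  tab <- read_delim_auto(path)
  req <- c("feature_id", "rt_min", "mz")
  if (!all(req %in% names(tab))) {
    stop("coordinate file needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(feature_id = as.character(tab$feature_id),
                        rt = as.numeric(tab$rt_min),
                        mz = as.numeric(tab$mz))
  validate_coordinates(out)
}

validate_coordinates <- function(coords) {
  coords <- tibble::as_tibble(coords)
  req <- c("feature_id", "rt", "mz")
  if (!all(req %in% names(coords))) {
    stop("feature coordinates need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(coords$feature_id)) {
    stop("duplicate feature_id in coordinates", call. = FALSE)
  }
  if (any(!is.finite(coords$rt)) || any(!is.finite(coords$mz)) ||
      any(coords$rt <= 0) || any(coords$mz <= 0)) {
    stop("retention times and m/z values must be positive and finite",
         call. = FALSE)
  }
  coords[, req]
}

#' Fit initial alignment parameters from anchor pairs
#'
#' Maximum-likelihood fit of the shift/scale Gaussian model on a small set
#' of features identified in both datasets: per-dimension least squares of
#' target coordinates on source coordinates, with the precision taken as
#' the inverse of the anchor residual covariance (regularized by a small
#' floor so exact anchors do not produce an infinite precision).
#'
#' @param source,target Coordinate tibbles (\code{feature_id}, \code{rt},
#'   \code{mz}) of equal length; row i of \code{source} pairs with row i of
#'   \code{target}.
#' @param prior_match Prior probability that a source feature is present in
#'   the target dataset (the greedy stopping rule's prior; default 0.5).
#' @param var_floor Lower bound on residual variances.
#' @return A list of class \code{mp_alignment_params} with \code{shift},
#'   \code{scale} (2-vectors, rt then mz), \code{precision} (2x2) and
#'   \code{prior_match}.
#' @export
fit_initial_params <- function(source, target, prior_match = 0.5,
                               var_floor = 1e-8) {
  source <- validate_coordinates(source)
  target <- validate_coordinates(target)
  stopifnot(nrow(source) == nrow(target), prior_match > 0, prior_match < 1)
  n <- nrow(source)
  if (n < 3) stop("need at least 3 anchor pairs", call. = FALSE)
  if (stats::sd(source$rt) == 0 || stats::sd(source$mz) == 0) {
    stop("degenerate anchors: no spread in a source dimension", call. = FALSE)
  }
  fit_rt <- stats::lm(target$rt ~ source$rt)
  fit_mz <- stats::lm(target$mz ~ source$mz)
  shift <- c(rt = unname(stats::coef(fit_rt)[1]),
             mz = unname(stats::coef(fit_mz)[1]))
  scale <- c(rt = unname(stats::coef(fit_rt)[2]),
             mz = unname(stats::coef(fit_mz)[2]))
  res <- cbind(stats::resid(fit_rt), stats::resid(fit_mz))
  covm <- crossprod(res) / n
  covm[1, 1] <- max(covm[1, 1], var_floor)
  covm[2, 2] <- max(covm[2, 2], var_floor)
  # keep the covariance positive definite
  off_max <- sqrt(covm[1, 1] * covm[2, 2]) * 0.999
  covm[1, 2] <- covm[2, 1] <- sign(covm[1, 2]) * min(abs(covm[1, 2]), off_max)
  structure(
    list(shift = shift, scale = scale, precision = solve(covm),
         prior_match = prior_match),
    class = "mp_alignment_params"
  )
}

# log density of target coords under the Gaussian match model for every
# (source, target) pair; returns an n_s x n_t matrix
match_loglik_matrix <- function(source, target, params) {
  pr <- params$precision
  logdet <- determinant(pr, logarithm = TRUE)$modulus[1]
  pred_rt <- params$shift["rt"] + params$scale["rt"] * source$rt
  pred_mz <- params$shift["mz"] + params$scale["mz"] * source$mz
  d1 <- outer(pred_rt, target$rt, `-`)
  d2 <- outer(pred_mz, target$mz, `-`)
  quad <- pr[1, 1] * d1^2 + 2 * pr[1, 2] * d1 * d2 + pr[2, 2] * d2^2
  -log(2 * pi) + 0.5 * logdet - 0.5 * quad
}

# log of the uniform background density over the bounding box of observed
# target coordinates (the non-match alternative in the stopping rule)
background_logdens <- function(source, target, params) {
  pred_rt <- params$shift["rt"] + params$scale["rt"] * source$rt
  pred_mz <- params$shift["mz"] + params$scale["mz"] * source$mz
  rt_all <- c(pred_rt, target$rt)
  mz_all <- c(pred_mz, target$mz)
  -log(max(diff(range(rt_all)), 1e-6)) - log(max(diff(range(mz_all)), 1e-6))
}

#' Greedy one-to-one matching of features across datasets
#'
#' Candidate pairs are ranked by match log-likelihood and accepted
#' best-first under the one-to-one constraint.  A pair is accepted only
#' while its posterior odds of being a true match -- Gaussian match
#' likelihood against a uniform background density over the bounding box of
#' observed coordinates, at prior odds
#' \code{prior_match / (1 - prior_match)} -- exceed 1; everything else is
#' reported unmatched.
#'
#' @param source,target Coordinate tibbles.
#' @param params Fitted [fit_initial_params()] parameters.
#' @return A list of class \code{mp_alignment} with \code{matches} (tibble
#'   of source_id, target_id, log_lik), \code{unmatched_source},
#'   \code{unmatched_target} and \code{params}.
#' @export
greedy_match <- function(source, target, params) {
  source <- validate_coordinates(source)
  target <- validate_coordinates(target)
  stopifnot(inherits(params, "mp_alignment_params"))
  if (nrow(source) == 0 || nrow(target) == 0) {
    return(structure(
      list(matches = tibble::tibble(source_id = character(),
                                    target_id = character(),
                                    log_lik = numeric()),
           unmatched_source = source$feature_id,
           unmatched_target = target$feature_id,
           params = params),
      class = "mp_alignment"))
  }
  ll <- match_loglik_matrix(source, target, params)
  bg <- background_logdens(source, target, params)
  threshold <- bg - log(params$prior_match / (1 - params$prior_match))
  cand <- which(ll > threshold, arr.ind = TRUE)
  ord <- order(ll[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  used_s <- logical(nrow(source)); used_t <- logical(nrow(target))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_s[i] && !used_t[j]) {
      used_s[i] <- TRUE; used_t[j] <- TRUE; keep[r] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  structure(
    list(matches = tibble::tibble(
           source_id = source$feature_id[cand[, 1]],
           target_id = target$feature_id[cand[, 2]],
           log_lik = ll[cand]),
         unmatched_source = source$feature_id[!used_s],
         unmatched_target = target$feature_id[!used_t],
         params = params),
    class = "mp_alignment"
  )
}

#' @export
print.mp_alignment <- function(x, ...) {
  cat(sprintf("<mp_alignment> %d matches, %d/%d unmatched (source/target)\n",
              nrow(x$matches), length(x$unmatched_source),
              length(x$unmatched_target)))
  cat(sprintf("  shift (%.3f, %.4f), scale (%.3f, %.4f)\n",
              x$params$shift[1], x$params$shift[2],
              x$params$scale[1], x$params$scale[2]))
  invisible(x)
}

#' Align two datasets and merge their intensity matrices
#'
#' Fits the shift/scale model from anchors (features identified identically
#' in both datasets, or an explicit anchor table), matches features
#' greedily, refits the parameters once from all accepted matches, matches
#' again, and merges: matched rows are joined into one row over the union
#' of samples; unmatched rows are carried with missing entries for the
#' absent dataset.
#'
#' @param x,y [mp_intensity] objects on the same scale.
#' @param x_coords,y_coords Coordinate tibbles covering the rows of
#'   \code{x} and \code{y}.
#' @param x_ids,y_ids Optional identification tibbles; features whose
#'   (peptide, protein) identification is unique in each dataset and shared
#'   across both serve as anchors.
#' @param anchors Optional explicit anchor tibble with columns
#'   \code{source_id}, \code{target_id} (used when identifications are not
#'   supplied).
#' @param prior_match Prior match probability for the stopping rule.
#' @return A list with \code{intensity} (merged [mp_intensity]) and
#'   \code{alignment} (the final [greedy_match()] map).
#' @export
align_datasets <- function(x, y, x_coords, y_coords,
                           x_ids = NULL, y_ids = NULL, anchors = NULL,
                           prior_match = 0.5) {
  stopifnot(inherits(x, "mp_intensity"), inherits(y, "mp_intensity"))
  if (x$raw != y$raw) stop("datasets are on different scales", call. = FALSE)
  x_coords <- validate_coordinates(x_coords)
  y_coords <- validate_coordinates(y_coords)
  if (!all(rownames(x$values) %in% x_coords$feature_id) ||
      !all(rownames(y$values) %in% y_coords$feature_id)) {
    stop("coordinates missing for some isotope groups", call. = FALSE)
  }
  x_coords <- x_coords[match(rownames(x$values), x_coords$feature_id), ]
  y_coords <- y_coords[match(rownames(y$values), y_coords$feature_id), ]

  if (is.null(anchors)) {
    if (is.null(x_ids) || is.null(y_ids)) {
      stop("supply either identifications for both datasets or an anchor table",
           call. = FALSE)
    }
    anchors <- shared_identification_anchors(x_ids, y_ids)
  }
  src_anchor <- x_coords[match(anchors$source_id, x_coords$feature_id), ]
  tgt_anchor <- y_coords[match(anchors$target_id, y_coords$feature_id), ]
  ok <- stats::complete.cases(src_anchor$rt, tgt_anchor$rt)
  params <- fit_initial_params(src_anchor[ok, ], tgt_anchor[ok, ],
                               prior_match = prior_match)

  map1 <- greedy_match(x_coords, y_coords, params)
  # one refit from all accepted matches, then a final matching pass
  if (nrow(map1$matches) >= 3) {
    src2 <- x_coords[match(map1$matches$source_id, x_coords$feature_id), ]
    tgt2 <- y_coords[match(map1$matches$target_id, y_coords$feature_id), ]
    params <- tryCatch(
      fit_initial_params(src2, tgt2, prior_match = prior_match),
      error = function(e) params)
  }
  map <- greedy_match(x_coords, y_coords, params)

  merged <- merge_aligned(x, y, map)
  list(intensity = merged, alignment = map)
}

shared_identification_anchors <- function(x_ids, y_ids) {
  x_ids <- validate_identifications(x_ids)
  y_ids <- validate_identifications(y_ids)
  key <- function(t) paste(t$peptide_sequence, t$protein_accession, sep = "|")
  xk <- key(x_ids); yk <- key(y_ids)
  shared <- intersect(xk[!duplicated(xk) & !(xk %in% xk[duplicated(xk)])],
                      yk[!duplicated(yk) & !(yk %in% yk[duplicated(yk)])])
  if (length(shared) < 3) {
    stop("fewer than 3 shared unique identifications to anchor on",
         call. = FALSE)
  }
  tibble::tibble(
    source_id = x_ids$isotope_group_id[match(shared, xk)],
    target_id = y_ids$isotope_group_id[match(shared, yk)])
}

merge_aligned <- function(x, y, map) {
  xs <- colnames(x$values); ys <- colnames(y$values)
  ys_out <- ifelse(ys %in% xs, paste0(ys, "_2"), ys)
  n1 <- length(xs); n2 <- length(ys)
  m <- map$matches
  row_ids <- c(m$source_id, map$unmatched_source, map$unmatched_target)
  vals <- matrix(NA_real_, length(row_ids), n1 + n2,
                 dimnames = list(row_ids, c(xs, ys_out)))
  miss <- matrix(TRUE, length(row_ids), n1 + n2,
                 dimnames = dimnames(vals))
  src_rows <- c(m$source_id, map$unmatched_source)
  vals[src_rows, seq_len(n1)] <- x$values[src_rows, , drop = FALSE]
  miss[src_rows, seq_len(n1)] <- x$missing[src_rows, , drop = FALSE]
  tgt_rows_out <- c(m$source_id, map$unmatched_target)
  tgt_rows_in <- c(m$target_id, map$unmatched_target)
  vals[tgt_rows_out, n1 + seq_len(n2)] <- y$values[tgt_rows_in, , drop = FALSE]
  miss[tgt_rows_out, n1 + seq_len(n2)] <- y$missing[tgt_rows_in, , drop = FALSE]
  samples <- dplyr::bind_rows(
    x$samples,
    dplyr::mutate(y$samples, sample_id = ys_out))
  mp_intensity(vals, missing = miss, raw = x$raw, log_base = x$log_base,
               samples = samples)
}

#' Write an alignment map to disk
#'
#' Matches as TSV (source_id, target_id, log_lik) plus a JSON parameter
#' block (shift, scale, precision, prior).
#'
#' @param map An [greedy_match()] result.
#' @param path Output TSV path; the JSON block goes to
#'   \code{<path>.params.json}.
#' @return \code{map}, invisibly.
#' @export
write_alignment <- function(map, path) {
  stopifnot(inherits(map, "mp_alignment"))
  readr::write_tsv(map$matches, path, progress = FALSE)
  pj <- list(shift = as.list(map$params$shift),
             scale = as.list(map$params$scale),
             precision = unclass(as.data.frame(map$params$precision)),
             prior_match = map$params$prior_match,
             n_matches = nrow(map$matches),
             n_unmatched_source = length(map$unmatched_source),
             n_unmatched_target = length(map$unmatched_target))
  jsonlite::write_json(pj, paste0(path, ".params.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(map)
}
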