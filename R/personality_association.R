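# Associations between mean first-impression ratings and self-reported
# personality scores: Pearson correlations with permutation significance,
# and the individual-judge analysis showing that group-level effect sizes
# are inflated relative to per-judge correlations.

#' The 17 self-report personality traits
#'
#' Trait vocabulary of the 1-10 scaled personality questionnaire (a Big
#' Five-covering instrument). Only the first five are tied to facial latent
#' factors in the default synthetic cohort; the vocabulary is configurable
#' in all loaders.
#' @export
PERSONALITY_TRAITS <- c("Trusting", "Striving", "Shaping",
                        "Openness to Experience", "Emotional Stability",
                        "Sociability", "Assertiveness", "Energy", "Modesty",
                        "Cooperation", "Discipline", "Ambition", "Creativity",
                        "Analytical", "Resilience", "Attention to Detail",
                        "Independence")

#' Permutation test for a Pearson correlation
#'
#' Two-sided: `y` is permuted `n_perm` times with `x` fixed and the p-value
#' is `(1 + #(|r_perm| >= |r_obs|)) / (n_perm + 1)` (add-one convention, so
#' p is never exactly 0).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `r` (observed), `p`, `n_perm`.
#' @export
permutation_test <- function(x, y, n_perm = 10000L, seed = 1L) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (stats::sd(x) < .Machine$double.eps || stats::sd(y) < .Machine$double.eps)
    stop("constant input; correlation undefined")
  r_obs <- stats::cor(x, y)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) abs(stats::cor(x, sample(y))) >= abs(r_obs),
               logical(1)))
  })
  list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = as.integer(n_perm))
}

#' Correlate mean ratings with personality scores for one gender
#'
#' Pearson correlations between every rating trait and every personality
#' trait on the ratees having both data types (pairwise complete; missing
#' personality participants are dropped, not imputed). Significance comes
#' from [permutation_test()]; the display mask keeps cells with
#' `|r| >= r_threshold` and `p < p_threshold`.
#'
#' @param means `mean_ratings` object.
#' @param pers data.frame with `ratee_id` and one column per personality
#'   trait (wide), or long format `ratee_id`, `trait`, `score`.
#' @param genders data.frame `ratee_id`, `gender`; `gender` selects ratees.
#' @param gender "F" or "M".
#' @param r_threshold,p_threshold display-mask thresholds (0.20, 0.01).
#' @param n_perm,seed permutation settings.
#' @return list of class `association_result`: `r` (rating x personality
#'   matrix), `p` (permutation p-values), `mask` (logical), `n` (ratees
#'   used), `gender`.
#' @export
correlate_ratings_personality <- function(means, pers, genders, gender,
                                          r_threshold = 0.20,
                                          p_threshold = 0.01,
                                          n_perm = 10000L, seed = 1L) {
  P <- personality_wide(pers)
  M <- means$means
  gg <- genders$gender[match(rownames(M), as.character(genders$ratee_id))]
  ids <- intersect(rownames(M)[gg == gender], rownames(P))
  if (length(ids) < 10L) stop("need >= 10 ratees with both data types")
  M <- M[ids, , drop = FALSE]; P <- P[ids, , drop = FALSE]
  if (any(apply(P, 2, stats::sd) < .Machine$double.eps))
    stop("constant personality column")
  r <- stats::cor(M, P)
  p <- r; p[] <- NA_real_
  for (i in seq_len(ncol(M))) for (j in seq_len(ncol(P))) {
    p[i, j] <- permutation_test(M[, i], P[, j], n_perm = n_perm,
                                seed = derive_seed(seed, i * 100L + j))$p
  }
  structure(list(r = r, p = p, mask = abs(r) >= r_threshold & p < p_threshold,
                 n = length(ids), gender = gender),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Rating-personality associations (gender %s, n = %d): %d of %d significant\n",
              x$gender, x$n, sum(x$mask), length(x$mask)))
  invisible(x)
}

# accept wide (ratee_id + trait columns) or long (ratee_id, trait, score)
personality_wide <- function(pers) {
  if (all(c("ratee_id", "trait", "score") %in% names(pers)) &&
      ncol(pers) == 3L) {
    traits <- intersect(PERSONALITY_TRAITS, unique(pers$trait))
    if (!length(traits)) traits <- sort(unique(pers$trait))
    ids <- sort(unique(pers$ratee_id))
    P <- tapply(pers$score,
                list(factor(pers$ratee_id, ids), factor(pers$trait, traits)),
                mean)
  } else {
    ids <- pers$ratee_id
    P <- as.matrix(pers[setdiff(names(pers), "ratee_id")])
    rownames(P) <- as.character(ids)
  }
  if (any(P < 1 - 1e-9 | P > 10 + 1e-9, na.rm = TRUE))
    stop("personality scores must lie in 1-10")
  P
}

#' Per-judge correlations between raw ratings and personality
#'
#' For each (rating trait, personality trait) pair, the Pearson correlation
#' is computed separately per judge on only the ratees that judge rated;
#' the mean, SD and a normal-approximation 95% interval across judges
#' summarise the individual-level effect. Because each judge rates only a
#' small subset, these per-judge correlations are attenuated and noisy
#' compared to the group-level correlation on averaged ratings.
#'
#' @param table long rating table.
#' @param pers personality table (wide or long; see
#'   [correlate_ratings_personality()]).
#' @param genders optional `ratee_id`/`gender` data.frame to restrict to one
#'   gender via `gender`.
#' @param gender optional gender filter.
#' @param pairs data.frame with columns `rating`, `personality` naming the
#'   trait pairs to analyse; default: all rating traits crossed with the
#'   personality traits present.
#' @param min_n minimum rated-subset size for a judge to enter (default 4).
#' @return data.frame: `rating`, `personality`, `mean_r`, `sd_r`, `lo`,
#'   `hi` (95% interval), `n_judges`, `n_excluded`.
#' @export
judge_level_correlations <- function(table, pers, genders = NULL,
                                     gender = NULL, pairs = NULL,
                                     min_n = 4L) {
  validate_rating_table(table)
  P <- personality_wide(pers)
  if (!is.null(gender)) {
    keep <- genders$ratee_id[genders$gender == gender]
    table <- table[table$ratee_id %in% keep, , drop = FALSE]
  }
  if (is.null(pairs))
    pairs <- expand.grid(rating = intersect(RATING_TRAITS, unique(table$trait)),
                         personality = colnames(P),
                         stringsAsFactors = FALSE)
  out <- vector("list", nrow(pairs))
  for (row in seq_len(nrow(pairs))) {
    rt <- pairs$rating[row]; pt <- pairs$personality[row]
    sub <- table[table$trait == rt, , drop = FALSE]
    sub <- sub[as.character(sub$ratee_id) %in% rownames(P), , drop = FALSE]
    rs <- c(); excluded <- 0L
    for (jd in split(sub, sub$judge_id)) {
      if (nrow(jd) < min_n) { excluded <- excluded + 1L; next }
      y <- P[as.character(jd$ratee_id), pt]
      if (stats::sd(jd$score) < .Machine$double.eps ||
          stats::sd(y) < .Machine$double.eps) { excluded <- excluded + 1L; next }
      rs <- c(rs, stats::cor(jd$score, y))
    }
    if (!length(rs)) stop("no judge meets the minimum subset size")
    m <- mean(rs); s <- stats::sd(rs)
    out[[row]] <- data.frame(rating = rt, personality = pt, mean_r = m,
                             sd_r = s,
                             lo = m - 1.96 * s / sqrt(length(rs)),
                             hi = m + 1.96 * s / sqrt(length(rs)),
                             n_judges = length(rs), n_excluded = excluded)
  }
  do.call(rbind, out)
}
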