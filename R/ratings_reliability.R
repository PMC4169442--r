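# First-impression ratings: averaging judge scores, inter-rater reliability
# (Cronbach's alpha with judges as items), the trait correlation network,
# its clusters, and gender contrasts.

#' The twelve first-impression rating traits
#'
#' Canonical trait vocabulary for the 1-9 Likert rating questionnaire
#' ("How \[trait\] does this person look").
#' @export
RATING_TRAITS <- c("Friendly", "Trustworthy", "Adventurous", "Temperamental",
                   "Physically Healthy", "Extraverted", "Dominating",
                   "Attractive", "Masculine", "Emotionally Stable",
                   "Responsible", "Intelligent")

validate_rating_table <- function(table) {
  need <- c("judge_id", "ratee_id", "trait", "score")
  if (!all(need %in% names(table)))
    stop("rating table needs columns ", paste(need, collapse = ", "))
  if (nrow(table) == 0L) stop("rating table is empty")
  bad <- which(!(table$score %in% 1:9))
  if (length(bad))
    stop("scores must be integers 1-9; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  unknown <- setdiff(unique(table$trait), RATING_TRAITS)
  if (length(unknown))
    stop("unknown trait name(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(table[c("judge_id", "ratee_id", "trait")]))
    stop("duplicate (judge, ratee, trait) entries")
  if (any(table$judge_id == table$ratee_id))
    stop("a judge never rates themself")
  invisible(table)
}

#' Average judge scores into mean ratings
#'
#' The mean over the ~20 judges of each ratee is the per-ratee trait score
#' used in all downstream analyses (the averaged first impressions).
#'
#' @param table long-format rating data.frame with columns `judge_id`,
#'   `ratee_id`, `trait`, `score` (integer 1-9).
#' @return list of class `mean_ratings`: `means` (ratee x trait matrix) and
#'   `n_judges` (matching matrix of contributing judge counts).
#' @export
mean_ratings <- function(table) {
  validate_rating_table(table)
  traits <- intersect(RATING_TRAITS, unique(table$trait))
  ratees <- sort(unique(table$ratee_id))
  f_r <- factor(table$ratee_id, levels = ratees)
  f_t <- factor(table$trait, levels = traits)
  means <- tapply(table$score, list(f_r, f_t), mean)
  n <- tapply(table$score, list(f_r, f_t), length)
  n[is.na(n)] <- 0L
  if (any(n == 0L))
    stop("some ratee x trait cells have zero judges")
  structure(list(means = means, n_judges = n), class = "mean_ratings")
}

#' @export
print.mean_ratings <- function(x, ...) {
  cat(sprintf("Mean ratings: %d ratees x %d traits (judges per cell %d-%d)\n",
              nrow(x$means), ncol(x$means), min(x$n_judges), max(x$n_judges)))
  invisible(x)
}

#' Cronbach's alpha of a judges x ratees score matrix
#'
#' Internal-consistency coefficient with judges as items and ratees as
#' cases: `alpha = k/(k-1) * (1 - sum(var_judge) / var(total))`, where
#' `var_judge` is each judge row's variance across ratees and `var(total)`
#' the variance of the per-ratee sum over judges.
#'
#' @param scores numeric matrix, judges in rows, ratees in columns.
#' @return alpha (scalar, <= 1).
#' @export
cronbach_alpha <- function(scores) {
  scores <- as.matrix(scores)
  k <- nrow(scores)
  if (k < 2L) stop("alpha needs at least 2 judges")
  total_var <- stats::var(colSums(scores))
  if (total_var < .Machine$double.eps)
    stop("zero total variance; alpha undefined")
  item_var <- apply(scores, 1, stats::var)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' Inter-rater reliability per trait and gender
#'
#' The rating design is incomplete (each ratee is scored by its own ~20
#' judges, no complete judge x ratee cross), so a complete matrix for alpha
#' does not exist. The default scheme builds a pseudo-complete matrix per
#' trait x gender: with k the minimum number of judges any ratee has, k
#' scores per ratee are subsampled (seeded) and treated as k parallel
#' "judge slots". The alternative `scheme = "icc"` estimates the
#' reliability of the k-judge mean from one-way variance components
#' (Spearman-Brown applied to ICC(1)).
#'
#' @param table long rating table (see [mean_ratings()]).
#' @param genders data.frame with `ratee_id`, `gender`.
#' @param scheme "subsample" (default) or "icc".
#' @param seed seed for the judge subsampling.
#' @return data.frame with `trait`, `gender`, `alpha`, `k` (judge slots).
#' @export
reliability <- function(table, genders, scheme = c("subsample", "icc"),
                        seed = 1L) {
  scheme <- match.arg(scheme)
  validate_rating_table(table)
  g <- genders$gender[match(table$ratee_id, genders$ratee_id)]
  if (anyNA(g)) stop("ratee(s) missing from the gender table")
  with_seed(seed, {
    out <- list()
    for (gender in sort(unique(genders$gender))) {
      sub_g <- table[g == gender, , drop = FALSE]
      for (trait in intersect(RATING_TRAITS, unique(sub_g$trait))) {
        sub <- sub_g[sub_g$trait == trait, , drop = FALSE]
        by_ratee <- split(sub$score, sub$ratee_id)
        k <- min(lengths(by_ratee))
        if (k < 2L) stop("fewer than 2 judges for some ratee (", trait, ")")
        M <- vapply(by_ratee, function(s) {
          # subsample k scores and shuffle so row i is a "judge slot",
          # not a particular judge (the design has no crossed judges)
          sample(s, k)
        }, numeric(k))
        alpha <- if (scheme == "subsample") cronbach_alpha(M)
                 else icc_alpha(M)
        out[[length(out) + 1L]] <- data.frame(trait = trait, gender = gender,
                                              alpha = alpha, k = k)
      }
    }
    do.call(rbind, out)
  })
}

# Spearman-Brown reliability of a k-judge mean from one-way ANOVA variance
# components (judge slots nested in ratee).
icc_alpha <- function(M) {
  k <- nrow(M); n <- ncol(M)
  ratee_means <- colMeans(M)
  msb <- k * stats::var(ratee_means)
  msw <- sum(sweep(M, 2, ratee_means)^2) / (n * (k - 1))
  icc1 <- (msb - msw) / (msb + (k - 1) * msw)
  k * icc1 / (1 + (k - 1) * icc1)
}

#' Correlation matrix of the mean ratings
#'
#' @param means a `mean_ratings` object or a ratee x trait matrix.
#' @param ratees optional subset of ratee ids (e.g. one gender).
#' @return trait x trait Pearson correlation matrix.
#' @export
rating_cor_matrix <- function(means, ratees = NULL) {
  M <- if (inherits(means, "mean_ratings")) means$means else as.matrix(means)
  if (!is.null(ratees)) M <- M[rownames(M) %in% as.character(ratees), , drop = FALSE]
  stats::cor(M)
}

#' Network of significant correlations between mean ratings
#'
#' Pairwise Pearson correlations among the trait means, computed per gender;
#' an edge is kept when it is significant in at least one gender, with scope
#' "both" when significant in both, else "men"/"women".
#'
#' @param means `mean_ratings` object.
#' @param genders data.frame with `ratee_id`, `gender` ("F"/"M").
#' @param p_threshold significance threshold for an edge (default 0.01).
#' @return data.frame of edges: `trait_a`, `trait_b`, `r_f`, `p_f`, `r_m`,
#'   `p_m`, `scope` ("both"/"women"/"men"), `sign` (of the significant r),
#'   class `rating_network`.
#' @export
rating_network <- function(means, genders, p_threshold = 0.01) {
  M <- means$means
  gg <- genders$gender[match(rownames(M), as.character(genders$ratee_id))]
  if (anyNA(gg)) stop("ratee(s) missing from the gender table")
  traits <- colnames(M)
  per_gender <- lapply(c(F_ = "F", M_ = "M"), function(gv) {
    Mg <- M[gg == gv, , drop = FALSE]
    if (nrow(Mg) < 3L) stop("need >= 3 ratees per gender")
    if (any(apply(Mg, 2, stats::sd) < .Machine$double.eps))
      stop("constant trait column")
    r <- stats::cor(Mg)
    n <- nrow(Mg)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    diag(p) <- 1
    list(r = r, p = p)
  })
  edges <- list()
  for (i in seq_along(traits)[-length(traits)]) for (j in (i + 1):length(traits)) {
    sig_f <- per_gender$F_$p[i, j] < p_threshold
    sig_m <- per_gender$M_$p[i, j] < p_threshold
    if (!sig_f && !sig_m) next
    scope <- if (sig_f && sig_m) "both" else if (sig_f) "women" else "men"
    r_ref <- if (sig_f) per_gender$F_$r[i, j] else per_gender$M_$r[i, j]
    edges[[length(edges) + 1L]] <- data.frame(
      trait_a = traits[i], trait_b = traits[j],
      r_f = per_gender$F_$r[i, j], p_f = per_gender$F_$p[i, j],
      r_m = per_gender$M_$r[i, j], p_m = per_gender$M_$p[i, j],
      scope = scope, sign = ifelse(r_ref >= 0, "positive", "negative"))
  }
  net <- if (length(edges)) do.call(rbind, edges) else
    data.frame(trait_a = character(), trait_b = character(),
               r_f = numeric(), p_f = numeric(), r_m = numeric(),
               p_m = numeric(), scope = character(), sign = character())
  class(net) <- c("rating_network", "data.frame")
  net
}

#' Cluster the rating traits by average-linkage on correlation distance
#'
#' Hierarchical clustering of the traits with distance `1 - r`, cut at `k`
#' clusters. Traits are ordered lexicographically before clustering so
#' linkage ties resolve deterministically.
#'
#' @param cor_mat trait x trait correlation matrix
#'   (see [rating_cor_matrix()]), or a `mean_ratings` object.
#' @param k number of clusters (default 3).
#' @return named integer vector: cluster membership per trait.
#' @export
cluster_ratings <- function(cor_mat, k = 3L) {
  if (inherits(cor_mat, "mean_ratings")) cor_mat <- rating_cor_matrix(cor_mat)
  traits <- sort(colnames(cor_mat))
  if (k > length(traits)) stop("k exceeds the trait count")
  cm <- cor_mat[traits, traits]
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  stats::cutree(hc, k = k)
}

#' Welch's t-test of mean ratings between genders, per trait
#'
#' @param means `mean_ratings` object.
#' @param genders data.frame with `ratee_id`, `gender` ("F"/"M").
#' @return data.frame: `trait`, `t` (positive when women score higher),
#'   `df` (Welch-Satterthwaite), `p` (two-sided), `direction`
#'   ("women_higher"/"men_higher"/"none").
#' @export
gender_difference_test <- function(means, genders) {
  M <- means$means
  gg <- genders$gender[match(rownames(M), as.character(genders$ratee_id))]
  if (anyNA(gg)) stop("ratee(s) missing from the gender table")
  if (min(table(gg)) < 2L) stop("need >= 2 ratees per gender")
  res <- lapply(colnames(M), function(trait) {
    x <- M[gg == "F", trait]; y <- M[gg == "M", trait]
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(trait = trait, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               direction = if (tt$p.value >= 0.05) "none"
                           else if (tt$statistic > 0) "women_higher"
                           else "men_higher")
  })
  do.call(rbind, res)
}
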