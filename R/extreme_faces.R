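# Extreme-face synthesis and forced-choice validation: the regression
# beta-coefficients define a direction in face-space; pushing the selected
# components to +/-4 SD renders faces predicted to sit at the ends of a
# trait's rating scale, which are then pitted against random faces.

#' Synthesize the low/high extreme face pair for a trait
#'
#' In the default `mode = "saturate"`, every component selected by the
#' regression model is set to `sign(beta_i) * magnitude` standard
#' deviations for the high face and its negation for the low face; all
#' other components stay at 0. `mode = "beta_weighted"` instead moves along
#' the beta direction, rescaled so the largest selected component sits at
#' `magnitude` SD. `magnitude = 2` reproduces the milder +/-2 SD displays
#' used to illustrate single components.
#'
#' @param model fitted `appearance_model`.
#' @param reg `regression_model` whose `indices` refer to the concatenated
#'   standardized shape+texture components of `model`.
#' @param magnitude SD multiple for the selected components (default 4).
#' @param mode "saturate" (default) or "beta_weighted".
#' @return object of class `extreme_pair`: `trait`, `gender`, `low`, `high`
#'   (each a [synthesize_face()] result), `settings_low`, `settings_high`
#'   (standardized component vectors), `predicted_low`, `predicted_high`.
#' @export
make_extreme_pair <- function(model, reg, magnitude = 4,
                              mode = c("saturate", "beta_weighted")) {
  mode <- match.arg(mode)
  n_comp <- model$shape_model$n_components + model$texture_model$n_components
  if (max(reg$indices) > n_comp)
    stop("regression indices exceed the model's component count")
  if (all(abs(reg$beta) < .Machine$double.eps))
    stop("all beta coefficients are zero")
  high <- numeric(n_comp)
  if (mode == "saturate") {
    high[reg$indices] <- sign(reg$beta) * magnitude
  } else {
    w <- reg$beta / max(abs(reg$beta))
    high[reg$indices] <- w * magnitude
  }
  low <- -high
  structure(list(trait = reg$trait, gender = reg$gender, mode = mode,
                 magnitude = magnitude,
                 settings_low = low, settings_high = high,
                 low = synthesize_face(model, standardized = low),
                 high = synthesize_face(model, standardized = high),
                 predicted_low = predict(reg, matrix(low, 1)),
                 predicted_high = predict(reg, matrix(high, 1))),
            class = "extreme_pair")
}

#' @export
print.extreme_pair <- function(x, ...) {
  cat(sprintf("Extreme pair%s (+/-%g SD, %s): predicted %.2f (low) vs %.2f (high)\n",
              if (is.na(x$trait)) "" else paste0(" for ", x$trait),
              x$magnitude, x$mode, x$predicted_low, x$predicted_high))
  invisible(x)
}

#' Draw a random face from a model's parameter space
#'
#' Each standardized component is drawn independently from a standard
#' normal truncated at +/-3 SD (simple rejection), so random comparison
#' faces never out-extreme a +/-4 SD extreme face along any single axis.
#'
#' @param model fitted `appearance_model`.
#' @param seed RNG seed; a fixed seed gives a bit-identical face.
#' @param truncate truncation bound in SD units (default 3).
#' @return list with `standardized` (component vector) and `face`
#'   (a [synthesize_face()] result).
#' @export
sample_random_face <- function(model, seed = 1L, truncate = 3) {
  n_comp <- model$shape_model$n_components + model$texture_model$n_components
  z <- with_seed(seed, rtrunc_norm(n_comp, truncate))
  list(standardized = z, face = synthesize_face(model, standardized = z))
}

# standard normal truncated at +/-b by rejection (b >= 1 makes this cheap)
rtrunc_norm <- function(n, b) {
  z <- stats::rnorm(n)
  while (any(bad <- abs(z) > b)) z[bad] <- stats::rnorm(sum(bad))
  z
}

#' Score a forced-choice validation question
#'
#' Respondents choose, among one extreme face and three random faces, the
#' face best expressing a trait; chance level is 1/4. An exact one-sided
#' binomial test asks whether the extreme face was chosen above chance.
#'
#' @param counts integer vector of length 4: choices for the extreme face
#'   first, then the three random faces.
#' @param trait,gender optional labels.
#' @return object of class `validation_result`: `n`, `counts`,
#'   `proportion`, `p` (exact binomial, alternative "greater").
#' @export
forced_choice_validation <- function(counts, trait = NA_character_,
                                     gender = NA_character_) {
  if (length(counts) != 4L || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be 4 non-negative integers (extreme face first)")
  n <- sum(counts)
  if (n < 1L) stop("need at least one respondent")
  p <- stats::binom.test(counts[1], n, p = 0.25,
                         alternative = "greater")$p.value
  structure(list(trait = trait, gender = gender, n = as.integer(n),
                 counts = as.integer(counts),
                 proportion = counts[1] / n, p = p),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Forced choice%s: extreme picked %d/%d (%.0f%%), binomial p = %.3g\n",
              if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$counts[1], x$n, 100 * x$proportion, x$p))
  invisible(x)
}

#' Simulate the forced-choice validation in silico
#'
#' Stand-in for a human validation event: each simulated judge receives the
#' extreme face plus three random faces, perceives each face's trait level
#' as the regression model's predicted score plus independent normal noise,
#' and picks the argmax (ties broken uniformly). With zero noise every
#' judge picks the extreme face; as noise dwarfs the predicted-score gap
#' the choice proportion approaches chance (1/4).
#'
#' @param model fitted `appearance_model`.
#' @param pair `extreme_pair` whose high face is the validation target.
#' @param reg the `regression_model` driving perception.
#' @param n_judges number of simulated respondents.
#' @param judge_noise SD of the perceptual noise, in rating-scale units.
#' @param seed RNG seed.
#' @return a `validation_result` (extreme face = the pair's high face).
#' @export
simulate_validation <- function(model, pair, reg, n_judges = 116L,
                                judge_noise = 1, seed = 1L) {
  n_comp <- model$shape_model$n_components + model$texture_model$n_components
  with_seed(seed, {
    counts <- integer(4)
    score_extreme <- drop(predict(reg, matrix(pair$settings_high, 1)))
    for (j in seq_len(n_judges)) {
      Z <- matrix(rtrunc_norm(3L * n_comp, 3), nrow = 3)
      scores <- c(score_extreme, drop(predict(reg, Z))) +
        stats::rnorm(4, sd = judge_noise)
      pick <- which(scores == max(scores))
      if (length(pick) > 1L) pick <- sample(pick, 1L)
      counts[pick] <- counts[pick] + 1L
    }
    forced_choice_validation(counts, trait = reg$trait, gender = reg$gender)
  })
}
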