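# Shared fixtures, built in code. The heavier cohorts are created once per
# test run and memoised so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# a small mixed-gender cohort for the rating/association/prediction tests
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(generative_spec(n_ratees = c(F = 40, M = 40)), seed = 101)
  })
}

# three-factor shape-recovery cohort plus its fitted model
three_factor_fit <- function() {
  fixture("three_factor_fit", function() {
    coh <- generate_cohort(three_factor_spec(n = 120), seed = 11)
    model <- build_appearance_model(coh$images, coh$landmarks, gender = "F",
                                    variance_retained = 0.99)
    list(cohort = coh, model = model)
  })
}

# a smooth synthetic gradient image for warp tests
gradient_image <- function(size = 48) {
  outer(seq(0, 1, length.out = size), seq(0, 1, length.out = size),
        function(a, b) 0.25 + 0.5 * a * b + 0.2 * sin(3 * a))
}

# simple square-ish landmark set inside a frame
square_shape <- function(margin = 8, size = 48) {
  as_landmark_shape(rbind(c(margin, margin), c(size - 1 - margin, margin),
                          c(size - 1 - margin, size - 1 - margin),
                          c(margin, size - 1 - margin),
                          c((size - 1) / 2, (size - 1) / 2)))
}

rotate_scale_shift <- function(shape, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * shape %*% t(R), 2, shift, "+")
}
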