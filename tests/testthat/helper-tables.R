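# Shared fixtures, built in code.

oral_tab <- function() oral_cancer_counts()

# random well-populated 2 x 4 table (all cells >= 5)
random_table <- function(seed) {
  set.seed(seed)
  count_table(cases = sample(5:120, 4, replace = TRUE),
              controls = sample(5:120, 4, replace = TRUE))
}

# glm fit of the product-term parameterization
# logit p = b0 + b1 A + b2 B + b3 A*B, the independent oracle for the
# combined-level model
product_term_fit <- function(tab) {
  d <- as_exposure_data(tab)
  a <- as.integer(d$level %in% c("A1B0", "A1B1"))
  b <- as.integer(d$level %in% c("A0B1", "A1B1"))
  f <- stats::glm(d$outcome ~ a * b, family = stats::binomial())
  list(beta = unname(stats::coef(f)),
       loglik = as.numeric(stats::logLik(f)))
}
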