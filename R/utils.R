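# internal: lm.fit on a multi-response matrix, with coefficients/residuals
# always returned as matrices (lm.fit drops to vectors for a single response)
fit_ols <- function(X, Yt) {
  fit <- stats::lm.fit(X, Yt)
  if (!is.matrix(fit$coefficients)) {
    fit$coefficients <- matrix(fit$coefficients, ncol = 1L,
                               dimnames = list(names(fit$coefficients), NULL))
  }
  if (!is.matrix(fit$residuals)) {
    fit$residuals <- matrix(fit$residuals, ncol = 1L)
  }
  fit
}
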