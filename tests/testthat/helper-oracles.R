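# Independent oracles used to cross-check the package's computations.

# OLS by explicit normal equations: solve(X'X) b = X'y, with classical
# standard errors. Deliberately avoids lm().
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(beta = drop(beta), se = se, rss = sum(resid^2), df = df)
}

# Externally studentized residual by a literal leave-one-out refit: for
# each i, fit without row i and scale the held-out prediction error.
loo_studentized_oracle <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  sapply(seq_len(n), function(i) {
    fit <- ols_oracle(X[-i, , drop = FALSE], y[-i])
    pred_i <- drop(X[i, , drop = FALSE] %*% fit$beta)
    s2 <- fit$rss / (n - 1 - p)
    h_i <- drop(X[i, , drop = FALSE] %*%
                  solve(crossprod(X[-i, , drop = FALSE]),
                        t(X[i, , drop = FALSE])))
    (y[i] - pred_i) / sqrt(s2 * (1 + h_i))
  })
}

# Mean and sd of a normal truncated to [a, b] (closed form).
truncnorm_moments <- function(mean, sd, a, b) {
  al <- (a - mean) / sd
  be <- (b - mean) / sd
  Z <- pnorm(be) - pnorm(al)
  m <- mean + sd * (dnorm(al) - dnorm(be)) / Z
  v <- sd^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                 ((dnorm(al) - dnorm(be)) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Standardized path coefficients recovered from the correlation matrix
# alone (covariance algebra for the just-identified recursive model).
path_oracle <- function(nem, stage, mbw, dmi) {
  R <- cor(cbind(nem = nem, stage = stage, mbw = mbw, dmi = dmi))
  b1 <- solve(R[c("nem", "stage"), c("nem", "stage")],
              R[c("nem", "stage"), "mbw"])
  b2 <- solve(R[c("nem", "stage", "mbw"), c("nem", "stage", "mbw")],
              R[c("nem", "stage", "mbw"), "dmi"])
  list(to_mbw = b1, to_dmi = b2)
}

# Small random cow table for property-style loops.
random_cows <- function(n, stage = "nonlactating", with_milk = FALSE) {
  df <- data.frame(
    stage = stage,
    sbw_kg = runif(n, 420, 730),
    diet_nem = runif(n, 0.93, 1.54),
    milk_kg_d = if (with_milk) runif(n, 3, 11.3) else NA_real_,
    stringsAsFactors = FALSE
  )
  cow_data(df)
}
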