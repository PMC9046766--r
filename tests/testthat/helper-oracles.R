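# Dense-matrix REML oracle for the intercept-only one-component model:
# evaluates the restricted log-likelihood directly from the n x n covariance
# matrix, profiling the residual variance, plus dense GLS/BLUP formulas.
denseREML <- function(y, Z, gamma) {
    n <- length(y)
    Z <- as.matrix(Z)
    H <- diag(n) + gamma * tcrossprod(Z)
    Hi <- solve(H)
    one <- rep(1, n)
    oneH1 <- drop(crossprod(one, Hi %*% one))
    oneHy <- drop(crossprod(one, Hi %*% y))
    yHy <- drop(crossprod(y, Hi %*% y))
    yPy <- yHy - oneHy^2 / oneH1
    s2e <- yPy / (n - 1)
    mu <- oneHy / oneH1
    loglik <- -0.5 * ((n - 1) * log(s2e) +
                      determinant(H, logarithm = TRUE)$modulus +
                      log(oneH1) + (n - 1) * (1 + log(2 * pi)))
    blup <- gamma * drop(crossprod(Z, Hi %*% (y - mu)))
    list(loglik = as.numeric(loglik), s2e = s2e, mu = mu, blup = blup)
}

# small random two-parent design in the shape buildParentDesign() produces
randomParentDesign <- function(n, nParents, seed, gammaTrue = 0.8) {
    set.seed(seed)
    pairs <- t(replicate(n, sample.int(nParents, 2)))
    Z <- Matrix::sparseMatrix(i = rep(seq_len(n), 2),
                              j = c(pairs[, 1], pairs[, 2]), x = 1,
                              dims = c(n, nParents))
    u <- rnorm(nParents, sd = sqrt(gammaTrue))
    y <- 3 + as.numeric(Z %*% u) + rnorm(n)
    new("ParentDesign", response = y, incidence = Z,
        parentIds = paste0("P", seq_len(nParents)), mode = "direct")
}

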