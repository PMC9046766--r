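#' @importFrom Matrix crossprod sparseMatrix Cholesky solve determinant
#'   rowSums colSums Diagonal
NULL

# REML for the intercept-only, one-variance-component mixed model
#   y = mu * 1 + Z u + e,  u ~ N(0, s2u I_q),  e ~ N(0, s2e I_n).
#
# The likelihood is profiled in the variance ratio gamma = s2u / s2e.
# Writing H = I + gamma Z Z', the restricted log-likelihood at the profiled
# residual variance s2e = y'Py/(n-1) is (p = 1 fixed effect)
#   lR = -1/2 [ (n-1) log s2e + log|H| + log(1'H^-1 1)
#               + (n-1) + (n-1) log 2pi ].
# All quantities come from the q x q system A = Z'Z + I/gamma via the
# Woodbury identity, so the cost per evaluation is one sparse Cholesky with
# a precomputed symbolic factorization:
#   H^-1 v     = v - Z A^-1 Z'v
#   log|H|     = q log gamma + log|A|
# The 1-D profile is maximized over log(gamma) with optimize(); a maximizer
# at the lower end of the interval is the boundary case s2u = 0.
.remlOneVariance <- function(y, Z, lowerLog = log(1e-10),
                             upperLog = log(1e6)) {
    n <- length(y)
    q <- ncol(Z)
    if (n != nrow(Z))
        stop("length(y) must equal nrow(Z)")
    if (n < 3L)
        stop("need at least 3 records")
    M <- Matrix::crossprod(Z)                 # q x q, symmetric sparse
    Zty <- as.numeric(Matrix::crossprod(Z, y))
    Zt1 <- as.numeric(Matrix::colSums(Z))
    yy <- sum(y * y)
    sy <- sum(y)
    ch0 <- Matrix::Cholesky(M, Imult = 1, LDL = FALSE, perm = TRUE)

    profile <- function(lg) {
        g <- exp(lg)
        ch <- Matrix::update(ch0, M, mult = 1 / g)
        ay <- as.numeric(Matrix::solve(ch, Zty, system = "A"))
        a1 <- as.numeric(Matrix::solve(ch, Zt1, system = "A"))
        yHy <- yy - sum(Zty * ay)
        oneH1 <- n - sum(Zt1 * a1)
        oneHy <- sy - sum(Zt1 * ay)
        yPy <- yHy - oneHy^2 / oneH1
        s2e <- yPy / (n - 1)
        logdetA <- as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                                  sqrt = FALSE)$modulus)
        logdetH <- q * lg + logdetA
        m2ll <- (n - 1) * log(s2e) + logdetH + log(oneH1) +
            (n - 1) * (1 + log(2 * pi))
        list(m2ll = m2ll, s2e = s2e, mu = oneHy / oneH1, ch = ch)
    }

    opt <- optimize(function(lg) profile(lg)$m2ll,
                    interval = c(lowerLog, upperLog), tol = 1e-8)
    atLower <- opt$minimum - lowerLog < 0.5
    atUpper <- upperLog - opt$minimum < 1e-3
    if (atLower) {
        # boundary: no detectable between-level variance
        mu <- sy / n
        s2e <- sum((y - mu)^2) / (n - 1)
        m2ll <- (n - 1) * log(s2e) + log(n) + (n - 1) * (1 + log(2 * pi))
        return(list(sigma2u = 0, sigma2e = s2e, mu = mu,
                    loglik = -m2ll / 2,
                    blup = numeric(q), gamma = 0, converged = TRUE,
                    boundary = TRUE))
    }
    g <- exp(opt$minimum)
    pr <- profile(opt$minimum)
    # BLUP: u = gamma Z' H^-1 (y - mu 1), via Z'H^-1 r = Z'r - M A^-1 Z'r
    Ztr <- Zty - pr$mu * Zt1
    u <- g * (Ztr - as.numeric(M %*% Matrix::solve(pr$ch, Ztr, system = "A")))
    list(sigma2u = g * pr$s2e, sigma2e = pr$s2e, mu = pr$mu,
         loglik = -pr$m2ll / 2, blup = u, gamma = g,
         converged = !atUpper, boundary = FALSE)
}

# indicator matrix from a 1-based group index
.indicatorMatrix <- function(index, nLevels) {
    Matrix::sparseMatrix(i = seq_along(index), j = index, x = 1,
                         dims = c(length(index), nLevels))
}
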