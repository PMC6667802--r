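CLIP_EPS <- 1e-3

clipFractions <- function(x) pmin(1 - CLIP_EPS, pmax(CLIP_EPS, x))

logEmission <- function(x, params) {
    cbind(stats::dbeta(x, params@shape1[1], params@shape2[1], log = TRUE),
          stats::dbeta(x, params@shape1[2], params@shape2[2], log = TRUE))
}

logSumExp <- function(a, b) {
    m <- pmax(a, b)
    m + log(exp(a - m) + exp(b - m))
}

#' Viterbi decoding of the two-state methylome HMM
#'
#' Maximum a posteriori joint state path in log space. Fractions are
#' clipped to [1e-3, 1 - 1e-3] before evaluating the Beta densities. Ties
#' break toward state 1 (background), making the decoder deterministic.
#'
#' @param fractions numeric vector of per-CpG methylation fractions.
#' @param params an \linkS4class{HmmParams}.
#' @return Integer vector of states (1 = background, 2 = PMD).
#' @export
viterbiPath <- function(fractions, params) {
    n <- length(fractions)
    if (n == 0L) stop("cannot decode an empty fraction sequence")
    x <- clipFractions(fractions)
    le <- logEmission(x, params)
    lA <- log(params@transMat)
    delta <- matrix(-Inf, n, 2)
    psi <- matrix(1L, n, 2)
    delta[1, ] <- log(params@initProb) + le[1, ]
    if (n > 1) for (t in 2:n) {
        for (j in 1:2) {
            cand <- delta[t - 1, ] + lA[, j]
            b <- which.max(cand)      # first max -> state 1 on ties
            psi[t, j] <- b
            delta[t, j] <- cand[b] + le[t, j]
        }
    }
    path <- integer(n)
    path[n] <- which.max(delta[n, ])
    if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
    path
}

# forward-backward in log space; returns log-likelihood, posteriors and
# expected transition counts
forwardBackward <- function(fractions, params) {
    x <- clipFractions(fractions)
    n <- length(x)
    le <- logEmission(x, params)
    lA <- log(params@transMat)
    la <- matrix(-Inf, n, 2)
    lb <- matrix(0, n, 2)
    la[1, ] <- log(params@initProb) + le[1, ]
    if (n > 1) {
        for (t in 2:n)
            la[t, ] <- le[t, ] +
                c(logSumExp(la[t - 1, 1] + lA[1, 1],
                            la[t - 1, 2] + lA[2, 1]),
                  logSumExp(la[t - 1, 1] + lA[1, 2],
                            la[t - 1, 2] + lA[2, 2]))
        for (t in (n - 1):1)
            lb[t, ] <- c(logSumExp(lA[1, 1] + le[t + 1, 1] + lb[t + 1, 1],
                                   lA[1, 2] + le[t + 1, 2] + lb[t + 1, 2]),
                         logSumExp(lA[2, 1] + le[t + 1, 1] + lb[t + 1, 1],
                                   lA[2, 2] + le[t + 1, 2] + lb[t + 1, 2]))
    }
    llForward <- logSumExp(la[n, 1], la[n, 2])
    llBackward <- logSumExp(log(params@initProb[1]) + le[1, 1] + lb[1, 1],
                            log(params@initProb[2]) + le[1, 2] + lb[1, 2])
    lg <- la + lb - llForward
    gamma <- exp(lg)
    xi <- matrix(0, 2, 2)
    if (n > 1) {
        for (i in 1:2) for (j in 1:2) {
            v <- la[1:(n - 1), i] + lA[i, j] + le[2:n, j] + lb[2:n, j] -
                llForward
            xi[i, j] <- sum(exp(v))
        }
    }
    list(logLik = llForward, logLikBackward = llBackward, gamma = gamma,
         xi = xi, x = x)
}

# expected complete-data log-likelihood contribution of one state's Beta
# emission, as a function of its sufficient statistics
betaQ <- function(a, b, sw, swlx, swl1x) {
    (a - 1) * swlx + (b - 1) * swl1x - sw * lbeta(a, b)
}

# M-step for one Beta emission: method-of-moments start, then numerical
# maximization of the weighted likelihood; falls back to the old shapes if
# no improvement (keeps EM monotone). Concentration capped at 1e4.
updateBeta <- function(w, x, aOld, bOld, concCap = 1e4) {
    sw <- sum(w)
    if (sw <= 0) return(c(aOld, bOld))
    mu <- sum(w * x) / sw
    v <- sum(w * (x - mu)^2) / sw
    swlx <- sum(w * log(x)); swl1x <- sum(w * log1p(-x))
    if (v < 1e-12) {
        conc <- concCap
        warning("degenerate emission data; concentration capped")
        cand <- c(mu * conc, (1 - mu) * conc)
    } else {
        conc <- min(concCap, max(1e-2, mu * (1 - mu) / v - 1))
        start <- log(c(mu * conc, (1 - mu) * conc))
        obj <- function(la) -betaQ(exp(la[1]), exp(la[2]), sw, swlx, swl1x)
        fit <- tryCatch(
            stats::optim(start, obj, method = "L-BFGS-B",
                         lower = log(1e-3), upper = log(concCap)),
            error = function(e) list(par = start))
        cand <- exp(fit$par)
    }
    if (betaQ(cand[1], cand[2], sw, swlx, swl1x) >=
        betaQ(aOld, bOld, sw, swlx, swl1x)) cand else c(aOld, bOld)
}

#' Baum-Welch estimation of the two-state methylome HMM
#'
#' Expectation-maximization with forward-backward recursions in log space.
#' Initial and transition probabilities use their closed-form M-step; each
#' state's Beta emission is re-estimated from the posterior-weighted data,
#' starting at the method-of-moments solution and refined by numerical
#' likelihood maximization (a candidate is only accepted when it does not
#' lower the EM objective, so the log-likelihood is non-decreasing at every
#' iteration). Iteration stops when the log-likelihood gain drops below
#' \code{tol} or after \code{maxIter} iterations; \code{maxIter = 0}
#' returns the initial parameters untouched.
#'
#' @param fractions numeric vector of per-CpG methylation fractions.
#' @param initParams starting \linkS4class{HmmParams}.
#' @param maxIter maximum EM iterations (default 50).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @return List with \code{params} (\linkS4class{HmmParams}),
#'   \code{logLikTrace} (per-iteration log-likelihood) and \code{nIter}.
#' @export
baumWelch <- function(fractions, initParams, maxIter = 50, tol = 1e-6) {
    params <- initParams
    trace <- numeric(0)
    if (maxIter == 0)
        return(list(params = params, logLikTrace = trace, nIter = 0L))
    for (it in seq_len(maxIter)) {
        fb <- forwardBackward(fractions, params)
        trace <- c(trace, fb$logLik)
        g <- fb$gamma; xi <- fb$xi; x <- fb$x
        piNew <- g[1, ] / sum(g[1, ])
        A <- params@transMat
        if (length(x) > 1) {
            rs <- rowSums(xi)
            for (i in 1:2) if (rs[i] > 0) A[i, ] <- xi[i, ] / rs[i]
        }
        e1 <- updateBeta(g[, 1], x, params@shape1[1], params@shape2[1])
        e2 <- updateBeta(g[, 2], x, params@shape1[2], params@shape2[2])
        params <- hmmParams(initProb = piNew, transMat = A,
                            shape1 = c(e1[1], e2[1]),
                            shape2 = c(e1[2], e2[2]))
        if (it > 1 && trace[it] - trace[it - 1] < tol) break
    }
    list(params = params, logLikTrace = trace, nIter = length(trace))
}

#' Call partially methylated domains
#'
#' Viterbi-decodes each chromosome and reports maximal runs of the PMD
#' state as regions spanning first to last member CpG, dropping runs
#' shorter than \code{minLenBp}.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param params an \linkS4class{HmmParams}
#'   (default \code{\link{defaultHmmParams}()}).
#' @param minLenBp minimum domain span in bp (default 10000).
#' @return A \linkS4class{RegionSet} of PMDs.
#' @export
callPmds <- function(methylome, params = defaultHmmParams(),
                     minLenBp = 10000) {
    byChrom <- perChromosome(methylome)
    out <- list()
    for (ch in names(byChrom)) {
        fr <- byChrom[[ch]]$fraction
        pos <- byChrom[[ch]]$pos
        path <- viterbiPath(fr, params)
        runs <- lowRuns(-path, -1.5)   # runs of state 2
        if (!nrow(runs)) next
        st <- pos[runs[, "start"]]; en <- pos[runs[, "end"]]
        keep <- (en - st + 1L) >= minLenBp
        if (!any(keep)) next
        runs <- runs[keep, , drop = FALSE]
        out[[length(out) + 1L]] <-
            GRanges(ch, IRanges(st[keep], en[keep]),
                    nCpg = runs[, "end"] - runs[, "start"] + 1L,
                    meanMeth = vapply(seq_len(nrow(runs)), function(i)
                        mean(fr[runs[i, "start"]:runs[i, "end"]]), 0))
    }
    if (!length(out)) {
        g <- GRanges()
        mcols(g) <- DataFrame(nCpg = integer(0), meanMeth = numeric(0),
                              regionType = character(0),
                              sizeBp = integer(0))
        return(RegionSet(g))
    }
    g <- GenomicRanges::sort(do.call(c, out), ignore.strand = TRUE)
    mcols(g)$regionType <- "PMD"
    mcols(g)$sizeBp <- width(g)
    RegionSet(g)
}

#' Persist and restore HMM parameters
#'
#' Plain-text key=value format.
#'
#' @param params an \linkS4class{HmmParams}.
#' @param path file path.
#' @return \code{readHmmParams}: an \linkS4class{HmmParams}.
#' @export
writeHmmParams <- function(params, path) {
    lines <- c(paste0("initProb=", paste(format(params@initProb,
                                                digits = 12),
                                         collapse = ",")),
               paste0("transMat=", paste(format(t(params@transMat),
                                                digits = 12),
                                         collapse = ",")),
               paste0("shape1=", paste(format(params@shape1, digits = 12),
                                       collapse = ",")),
               paste0("shape2=", paste(format(params@shape2, digits = 12),
                                       collapse = ",")))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeHmmParams
#' @export
readHmmParams <- function(path) {
    kv <- strsplit(readLines(path), "=", fixed = TRUE)
    vals <- lapply(kv, function(p)
        as.numeric(strsplit(p[2], ",", fixed = TRUE)[[1]]))
    names(vals) <- vapply(kv, `[`, "", 1L)
    hmmParams(initProb = vals$initProb,
              transMat = matrix(vals$transMat, 2, 2, byrow = TRUE),
              shape1 = vals$shape1, shape2 = vals$shape2)
}
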