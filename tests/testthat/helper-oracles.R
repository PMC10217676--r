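# Independent brute-force oracles: explicit voxel-enumeration loops and
# exhaustive scans, deliberately written without reusing the package's
# vectorized implementations.

oracleDice <- function(a, b) {
  na <- 0L; nb <- 0L; ni <- 0L
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1L
    if (b[i]) nb <- nb + 1L
    if (a[i] && b[i]) ni <- ni + 1L
  }
  if (na + nb == 0L) 1 else 2 * ni / (na + nb)
}

oracleIoU <- function(masks) {
  ni <- 0L; nu <- 0L
  for (i in seq_along(masks[[1]])) {
    inAll <- TRUE; inAny <- FALSE
    for (m in masks) {
      if (m[i]) inAny <- TRUE else inAll <- FALSE
    }
    if (inAll) ni <- ni + 1L
    if (inAny) nu <- nu + 1L
  }
  if (nu == 0L) 1 else ni / nu
}

oracleIoP <- function(masks, finalMask) {
  ni <- 0L; nf <- 0L
  for (i in seq_along(finalMask)) {
    inAll <- TRUE
    for (m in masks) if (!m[i]) inAll <- FALSE
    if (inAll) ni <- ni + 1L
    if (finalMask[i]) nf <- nf + 1L
  }
  if (nf == 0L) NA_real_ else ni / nf
}

oracleDCA <- function(masks, finalMask) {
  tot <- 0
  for (m in masks) tot <- tot + oracleDice(m, finalMask)
  tot / length(masks)
}

oracleDCM <- function(masks, finalMask) {
  d <- sort(vapply(masks, oracleDice, numeric(1), b = finalMask))
  n <- length(d)
  if (n %% 2L == 1L) d[(n + 1L) / 2L] else (d[n / 2L] + d[n / 2L + 1L]) / 2
}

oracleCV <- function(masks) {
  vols <- numeric(length(masks))
  for (k in seq_along(masks)) {
    n <- 0L
    for (i in seq_along(masks[[k]])) if (masks[[k]][i]) n <- n + 1L
    vols[k] <- n
  }
  mu <- sum(vols) / length(vols)
  if (mu == 0) return(NA_real_)
  sqrt(sum((vols - mu)^2) / (length(vols) - 1)) / mu
}

# Exhaustive threshold search with the same candidate set and tie rules,
# evaluated by direct counting.
oracleThreshold <- function(values, truth, weight, orientation) {
  v <- sort(unique(values))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  results <- lapply(cand, function(t) {
    flagged <- if (orientation == "higher_is_better") values < t else values > t
    se <- sum(flagged & truth == "insufficient") / sum(truth == "insufficient")
    sp <- sum(!flagged & truth == "sufficient") / sum(truth == "sufficient")
    list(threshold = t, se = se, sp = sp, j = weight * se + sp)
  })
  js <- vapply(results, `[[`, numeric(1), "j")
  ses <- vapply(results, `[[`, numeric(1), "se")
  ts <- vapply(results, `[[`, numeric(1), "threshold")
  keep <- which(js == max(js))
  keep <- keep[ses[keep] == max(ses[keep])]
  best <- if (orientation == "higher_is_better")
    keep[which.max(ts[keep])] else keep[which.min(ts[keep])]
  results[[best]]
}

randomMask <- function(dims, p = 0.35) {
  array(stats::runif(prod(dims)) < p, dims)
}

# small LabelMap built from a vector of voxel values
tinyLabelMap <- function(values, dims = c(3, 3, 1), scheme = shoulderScheme(),
                         spacing = c(1, 1, 1)) {
  LabelMap(array(as.integer(values), dims), spacing = spacing, scheme = scheme)
}

smallPhantom <- function(seed = 1, grid = 32) {
  makePhantom(phantomSpec(gridShape = rep(grid, 3), seed = seed))
}
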