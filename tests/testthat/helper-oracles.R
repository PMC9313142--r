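## Independent brute-force oracles. These deliberately share no code with
## the package internals: spheres are found by exhaustive distance tests,
## components by an explicit flood fill, ROC operating points by naive
## counting at every threshold.

## exhaustive SUVpeak: for every mask voxel, test all grid voxels by
## physical distance; centers whose sphere would leave the grid are
## skipped when at least one center admits a full sphere
brute_suv_peak <- function(values, spacing, mask_idx, diameter = 12) {
  d <- dim(values)
  r <- diameter / 2
  co <- arrayInd(mask_idx, d)
  ## offsets by exhaustive search over a generous cube
  rng <- lapply(1:3, function(a) -ceiling(r / spacing[a]):ceiling(r / spacing[a]))
  off <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  keep <- sqrt((off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
                 (off[, 3] * spacing[3])^2) <= r
  off <- off[keep, , drop = FALSE]
  full_ok <- function(cz, cy, cx) {
    all(cz + off[, 1] >= 1 & cz + off[, 1] <= d[1] &
        cy + off[, 2] >= 1 & cy + off[, 2] <= d[2] &
        cx + off[, 3] >= 1 & cx + off[, 3] <= d[3])
  }
  full <- mapply(full_ok, co[, 1], co[, 2], co[, 3])
  use_trunc <- !any(full)
  centers <- if (use_trunc) co else co[full, , drop = FALSE]
  best_val <- -Inf
  best_ctr <- NULL
  ## lexicographic (z,y,x) scan with strict improvement = first-max tie-break
  ord <- order(centers[, 1], centers[, 2], centers[, 3])
  for (i in ord) {
    zz <- centers[i, 1] + off[, 1]
    yy <- centers[i, 2] + off[, 2]
    xx <- centers[i, 3] + off[, 3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    v <- mean(values[cbind(zz[ok], yy[ok], xx[ok])])
    if (v > best_val + 1e-12) {
      best_val <- v
      best_ctr <- centers[i, ]
    }
  }
  list(value = best_val, center = best_ctr)
}

## flood-fill connected components; returns a list of sorted voxel-index
## vectors (partition representation, label-order independent)
flood_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  seen <- array(FALSE, d)
  comps <- list()
  for (start in which(mask)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      members <- c(members, cur)
      ci <- arrayInd(cur, d)
      for (j in seq_len(nrow(off))) {
        nz <- ci[1] + off[j, 1]; ny <- ci[2] + off[j, 2]; nx <- ci[3] + off[j, 3]
        if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] || nx < 1 || nx > d[3])
          next
        lin <- as.integer(nz + (ny - 1) * d[1] + (nx - 1) * d[1] * d[2])
        if (mask[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps[order(vapply(comps, min, 0))]
}

## partition representation of a label volume, for comparison with the oracle
labels_to_partition <- function(labels, drop_small_ml = 0, vox_ml = 1) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  comps <- lapply(ids, function(k) sort(which(labels == k)))
  comps <- comps[vapply(comps, length, 0L) * vox_ml >= drop_small_ml]
  comps[order(vapply(comps, min, 0))]
}

## naive all-thresholds ROC search with the package's stated tie rules
brute_roc <- function(scores, labels, min_spec = 0.80) {
  labels <- as.logical(labels)
  thr <- c(sort(unique(scores)), Inf)
  res <- data.frame(cutoff = thr, sens = NA_real_, spec = NA_real_)
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    res$sens[i] <- sum(pred & labels) / sum(labels)
    res$spec[i] <- sum(!pred & !labels) / sum(!labels)
  }
  j <- res$sens + res$spec - 1
  best <- which(abs(j - max(j)) < 1e-12)
  best <- best[abs(res$spec[best] - max(res$spec[best])) < 1e-12]
  best <- best[which.max(res$cutoff[best])]
  elig <- which(res$spec >= min_spec)
  ms <- elig[which.min(res$cutoff[elig])]
  ## AUC by pairwise comparison (Mann-Whitney, ties count 1/2)
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(cutoff_youden = res$cutoff[best], sens_youden = res$sens[best],
       spec_youden = res$spec[best], cutoff_minspec = res$cutoff[ms],
       sens_minspec = res$sens[ms], auc = mean(cmp))
}

## hand-coded logistic log-likelihood, for LRT oracles
logistic_loglik <- function(beta, X, y) {
  eta <- as.vector(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

## hand-coded Cox partial log-likelihood (no ties in the data used)
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

## small random phantom-like volume for oracle equivalence suites
random_volume <- function(dim, spacing = 2, seed = 1, hot_frac = 0.2) {
  set.seed(seed)
  v <- array(stats::runif(prod(dim), 0, 1), dim)
  hot <- sample(prod(dim), round(hot_frac * prod(dim)))
  v[hot] <- v[hot] + stats::runif(length(hot), 2, 6)
  suv_volume(v, spacing)
}
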