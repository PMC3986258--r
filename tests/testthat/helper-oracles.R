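# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately avoid the package's vectorized code paths:
# overlaps are enumerated with nested loops and the neck oracle re-derives
# the smoothed boundary-distance minima with explicit loops and its own
# breadth-first plateau search.

# build a label matrix from a character sketch: "." = background, letters
# and digits become regions (A=1, B=2, ..., or the digit itself)
sketch_frame <- function(rows) {
  grid <- do.call(rbind, lapply(strsplit(rows, ""), function(x) x))
  out <- matrix(0L, nrow(grid), ncol(grid))
  syms <- setdiff(sort(unique(as.vector(grid))), ".")
  for (k in seq_along(syms)) out[grid == syms[k]] <- k
  out
}

# brute-force weight-distribution scores by direct overlap enumeration
oracle_scores <- function(l1, l2) {
  ids1 <- setdiff(sort(unique(as.vector(l1))), 0L)
  ids2 <- setdiff(sort(unique(as.vector(l2))), 0L)
  ov <- matrix(0L, length(ids1), length(ids2),
               dimnames = list(ids1, ids2))
  for (i in seq_along(ids1)) {
    for (j in seq_along(ids2)) {
      ov[i, j] <- sum(l1 == ids1[i] & l2 == ids2[j])
    }
  }
  rel <- matrix(FALSE, length(ids1), length(ids2))
  for (i in seq_along(ids1)) {
    for (j in seq_along(ids2)) {
      if (ov[i, j] >= 1L &&
          (ov[i, j] == max(ov[, j]) || ov[i, j] == max(ov[i, ]))) {
        rel[i, j] <- TRUE
      }
    }
  }
  n_anc <- colSums(rel)
  s_later <- ifelse(n_anc > 0, 1 / n_anc, NA_real_)
  s_earlier <- rep(NA_real_, length(ids1))
  for (i in seq_along(ids1)) {
    js <- which(rel[i, ])
    if (length(js) > 0) s_earlier[i] <- sum(1 / n_anc[js])
  }
  list(earlier = stats::setNames(s_earlier, ids1),
       later = stats::setNames(s_later, ids2))
}

# naive neck detector: explicit-loop distance matrix, separable cyclic
# Gaussian smoothing by loops, weak-minima scan, BFS plateau grouping,
# the same arc exclusion and outside-neighbour rule as the definition
oracle_necks <- function(mask, kernel_px = 5L, pixel_size_um = 1) {
  ct <- mitodyn:::trace_contour(mask != 0)
  n <- nrow(ct)
  if (n < 12L) return(list(n_necks = 0L, min_width = NA_real_))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((ct[i, ] - ct[j, ])^2))
    }
  }
  half <- kernel_px %/% 2L
  w <- stats::dnorm(seq(-half, half), sd = kernel_px / 4)
  w <- w / sum(w)
  S1 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_along(w)) {
      S1[i, ] <- S1[i, ] + w[k] * D[((i - 1 + k - half - 1) %% n) + 1, ]
    }
  }
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_along(w)) {
      S[, j] <- S[, j] + w[k] * S1[, ((j - 1 + k - half - 1) %% n) + 1]
    }
  }
  tol <- 1e-9
  nb <- function(i, j) {
    out <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- rbind(out, c(((i - 1 + dr) %% n) + 1, ((j - 1 + dc) %% n) + 1))
    }
    out
  }
  arc <- function(i, j) min(abs(i - j), n - abs(i - j))
  cand <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (arc(i, j) < 3L * kernel_px) next
      nbs <- nb(i, j)
      if (all(S[i, j] <= S[nbs] + tol)) cand[i, j] <- TRUE
    }
  }
  if (!any(cand)) return(list(n_necks = 0L, min_width = NA_real_))
  seen <- matrix(FALSE, n, n)
  keys <- character(0)
  widths <- numeric(0)
  for (start in which(cand & !seen)) {
    ij <- arrayInd(start, c(n, n))
    if (seen[ij]) next
    # BFS over the plateau component
    queue <- list(c(ij[1], ij[2]))
    comp <- NULL
    seen[ij[1], ij[2]] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      comp <- rbind(comp, p)
      for (q in seq_len(8)) {
        nbs <- nb(p[1], p[2])
        qq <- nbs[q, ]
        if (cand[qq[1], qq[2]] && !seen[qq[1], qq[2]]) {
          seen[qq[1], qq[2]] <- TRUE
          queue[[length(queue) + 1]] <- qq
        }
      }
    }
    vmin <- min(S[comp])
    ok <- TRUE
    for (r in seq_len(nrow(comp))) {
      nbs <- nb(comp[r, 1], comp[r, 2])
      for (q in seq_len(8)) {
        if (!cand[nbs[q, 1], nbs[q, 2]] && S[nbs[q, 1], nbs[q, 2]] <= vmin + tol) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    canon <- cbind(pmin(comp[, 1], comp[, 2]), pmax(comp[, 1], comp[, 2]))
    canon <- canon[order(canon[, 1], canon[, 2]), , drop = FALSE]
    key <- paste(canon[, 1], canon[, 2], collapse = ";")
    if (key %in% keys) next
    keys <- c(keys, key)
    widths <- c(widths, min(D[comp]))
  }
  if (length(keys) == 0L) return(list(n_necks = 0L, min_width = NA_real_))
  list(n_necks = length(keys), min_width = min(widths) * pixel_size_um)
}

# minimal cross-boundary distance ignoring smoothing entirely: the global
# minimum of the raw pairwise boundary distances over pairs separated by at
# least min_arc along the contour
oracle_min_cross_distance <- function(mask, min_arc = 15L) {
  ct <- mitodyn:::trace_contour(mask != 0)
  n <- nrow(ct)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (min(j - i, n - (j - i)) < min_arc) next
      d <- sqrt(sum((ct[i, ] - ct[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# random label frame: k axis-aligned blobs painted in sequence
random_label_frame <- function(k, dim = c(30L, 30L)) {
  lab <- matrix(0L, dim[1], dim[2])
  for (id in seq_len(k)) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    r0 <- sample.int(dim[1] - h, 1)
    c0 <- sample.int(dim[2] - w, 1)
    lab[r0 + seq_len(h), c0 + seq_len(w)] <- id
  }
  # regions overwritten out of existence disappear; keep ids as painted
  lab
}

# perturb a label frame: shift every region by a small random offset
perturb_label_frame <- function(lab, max_shift = 3L) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    px <- which(lab == id, arr.ind = TRUE)
    dr <- sample(-max_shift:max_shift, 1)
    dc <- sample(-max_shift:max_shift, 1)
    r <- px[, 1] + dr; c <- px[, 2] + dc
    ok <- r >= 1 & r <= nrow(lab) & c >= 1 & c <= ncol(lab)
    out[cbind(r[ok], c[ok])] <- id
  }
  out
}
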