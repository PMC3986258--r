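# Connected-component labeling and contour tracing shared by the
# segmentation and morphometry code. Objects use 8-connectivity, holes use
# 4-connectivity (the complementary pairing that keeps the Euler
# characteristic consistent).

#' Label connected components of a binary mask
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 8 (default, used for objects) or 4 (used for holes).
#' @return Integer matrix of labels, 0 = background, labels numbered in
#'   column-major order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)  # 4-connected passes
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8) {
    # merge labels touching diagonally
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(pairs) > 0L) {
      g <- igraph::make_graph(edges = as.vector(t(pairs)), n = max(lab),
                              directed = FALSE)
      comp <- igraph::components(g)$membership
      lab[lab > 0L] <- comp[lab[lab > 0L]]
    }
  } else if (connectivity != 4) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  .relabel_sequential(lab)
}

# renumber labels 1..n in column-major order of first occurrence
.relabel_sequential <- function(lab) {
  ids <- unique(lab[lab > 0L])
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Count interior holes of a single region mask
#'
#' Holes are 4-connected background components not reachable from the image
#' border.
#' @param mask Logical matrix of one region.
#' @return Integer hole count.
#' @keywords internal
count_holes <- function(mask) {
  mask <- mask != 0
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  bg <- label_components(!pad, connectivity = 4)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  length(setdiff(unique(bg[bg > 0L]), border))
}

# Moore-neighbour contour tracing with Jacob's stopping criterion.
# Returns an n x 2 matrix of (row, col) of the outer boundary in traversal
# order (a closed cyclic walk; pixels on one-pixel-wide spurs appear twice,
# which is the natural closed-curve parameterization of the boundary).
trace_contour <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  # first foreground pixel scanning rows top to bottom, then left to right
  hit <- which(t(mask))[1]
  if (is.na(hit)) return(matrix(numeric(0), 0, 2))
  r0 <- ((hit - 1L) %/% nc) + 1L
  c0 <- ((hit - 1L) %% nc) + 1L
  # clockwise Moore neighbourhood starting West (rows grow downward)
  off <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
               c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  p <- c(r0, c0)
  bdir <- 1L  # direction index of the backtrack pixel relative to p (West)
  contour <- list(p)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(p[1], p[2], bdir, sep = ","), TRUE, envir = seen)
  max_steps <- 8L * (nr * nc + 1L)
  for (step in seq_len(max_steps)) {
    found <- FALSE
    k <- bdir
    for (j in 1:8) {
      k <- (k %% 8L) + 1L  # next clockwise
      q <- p + off[k, ]
      if (inside(q[1], q[2])) {
        # backtrack for the next pixel: the neighbour examined just before q,
        # expressed relative to q
        prevk <- if (k == 1L) 8L else k - 1L
        bpix <- p + off[prevk, ]
        d <- bpix - q
        bdir <- which(off[, 1] == d[1] & off[, 2] == d[2])
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    key <- paste(p[1], p[2], bdir, sep = ",")
    if (isTRUE(get0(key, envir = seen))) break  # walk state repeats: closed
    assign(key, TRUE, envir = seen)
    contour[[length(contour) + 1L]] <- p
  }
  do.call(rbind, contour)
}

# Boundary pixels of a region (pixels with a 4-neighbour outside the region),
# as an n x 2 (row, col) matrix in scan order.
boundary_pixels <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  shift_up    <- rbind(mask[-1, , drop = FALSE], FALSE)
  shift_down  <- rbind(FALSE, mask[-nr, , drop = FALSE])
  shift_left  <- cbind(mask[, -1, drop = FALSE], FALSE)
  shift_right <- cbind(FALSE, mask[, -nc, drop = FALSE])
  interior <- mask & shift_up & shift_down & shift_left & shift_right
  which(mask & !interior, arr.ind = TRUE)
}

# Perimeter (pixel units) of a region mask: length of the traced outer
# boundary polygon (1 per axial step, sqrt(2) per diagonal step). The
# edge-pixel-count variant multiplies the number of boundary pixels by one
# pixel length instead.
perimeter_px <- function(mask, edge_count = FALSE) {
  if (edge_count) return(nrow(boundary_pixels(mask)))
  ct <- trace_contour(mask)
  n <- nrow(ct)
  if (n < 2L) return(0)
  nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - ct)^2)))
}
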