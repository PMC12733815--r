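# Independent oracles used by the segmentation tests. These deliberately use
# a different algorithm (vectorised iterative label propagation in pure R)
# from the package's depth-first search in C++.

.circ_dist <- function(a, b, range = 180) {
  d <- abs(a - b)
  pmin(d, range - d)
}

# value of each pixel's neighbour at offset (dy, dx), NA off-image:
# out[y, x] = m[y + dy, x + dx]
.neighbour_at <- function(m, dy, dx) .shift_mat(m, -dy, -dx)

# shift a matrix by (dy, dx), padding with NA
.shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(NA_real_, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

.offsets8 <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                  c(0, 1), c(1, -1), c(1, 0), c(1, 1))

# Brute-force emulation of the hue-density clustering: same definition,
# different machinery. Returns a list like modified_dbscan()'s map.
bf_dbscan <- function(hue, eps, min_neighbors = 8L, edge_margin = 1L,
                      hue_range = 180) {
  H <- nrow(hue); W <- ncol(hue)
  nonedge <- matrix(FALSE, H, W)
  nonedge[(edge_margin + 1):(H - edge_margin),
          (edge_margin + 1):(W - edge_margin)] <- TRUE

  close_nb <- vector("list", 8L)
  cnt <- matrix(0L, H, W)
  for (k in seq_along(.offsets8)) {
    nb <- .neighbour_at(hue, .offsets8[[k]][1], .offsets8[[k]][2])
    cl <- !is.na(nb) & .circ_dist(hue, nb, hue_range) <= eps
    close_nb[[k]] <- cl
    cnt <- cnt + cl
  }
  core <- nonedge & cnt >= min_neighbors

  # flood minimum linear (row-major) label over valid core-core edges
  lin <- matrix(seq_len(H * W), H, W)      # any distinct labels work
  lab <- ifelse(core, lin, NA_real_)
  repeat {
    new <- lab
    for (k in seq_along(.offsets8)) {
      nb <- .neighbour_at(lab, .offsets8[[k]][1], .offsets8[[k]][2])
      ok <- core & !is.na(nb) & close_nb[[k]]
      new[ok] <- pmin(new[ok], nb[ok])
    }
    if (identical(new, lab)) break
    lab <- new
  }

  # boundary pixels: first close core neighbour in fixed offset order
  grp <- lab
  for (k in seq_along(.offsets8)) {
    nbcore <- .neighbour_at(core * 1, .offsets8[[k]][1], .offsets8[[k]][2])
    nblab <- .neighbour_at(lab, .offsets8[[k]][1], .offsets8[[k]][2])
    ok <- nonedge & !core & is.na(grp) &
      !is.na(nbcore) & nbcore == 1 & close_nb[[k]]
    grp[ok] <- nblab[ok]
  }
  labels <- matrix(-1L, H, W)
  labels[!is.na(grp)] <- 1L
  labels[core] <- 2L
  list(labels = labels, group_ids = grp, core = core)
}

# canonical partition signature: group ids renumbered 0.. in raster-scan
# (row-major) order of each group's first member pixel; -1 elsewhere
canonical_partition <- function(group_ids) {
  g <- group_ids
  g[is.na(g)] <- -1
  H <- nrow(g); W <- ncol(g)
  rm_order <- as.vector(t(g))            # row-major scan
  firsts <- !duplicated(rm_order) & rm_order >= 0
  ids <- rm_order[firsts]
  out <- matrix(-1L, H, W)
  for (i in seq_along(ids)) out[g == ids[i]] <- i - 1L
  out
}

# 8-connected components of a logical mask (same propagation machinery)
mask_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- ifelse(mask, matrix(seq_len(H * W), H, W), NA_real_)
  repeat {
    new <- lab
    for (k in seq_along(.offsets8)) {
      nb <- .neighbour_at(lab, .offsets8[[k]][1], .offsets8[[k]][2])
      ok <- mask & !is.na(nb)
      new[ok] <- pmin(new[ok], nb[ok])
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}
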