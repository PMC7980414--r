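# Independent brute-force oracles, deliberately naive and separate from the
# package's implementations.

# 4-connected components by explicit stack-based flood fill
flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1L] < 1L || p[1L] > nr || p[2L] < 1L || p[2L] > nc) next
        if (!mask[p[1L], p[2L]] || lab[p[1L], p[2L]] > 0L) next
        lab[p[1L], p[2L]] <- cur
        stack <- c(stack, list(c(p[1L] - 1L, p[2L]), c(p[1L] + 1L, p[2L]),
                               c(p[1L], p[2L] - 1L), c(p[1L], p[2L] + 1L)))
      }
    }
  }
  lab
}

# canonical form of a labeling: sorted list of sorted pixel-index sets
component_sets <- function(lab) {
  s <- lapply(split(which(lab > 0L), lab[lab > 0L]), sort)
  unname(s[order(vapply(s, min, 1L))])
}

# all-pairs pixel-set intersection overlap oracle
overlap_oracle <- function(setA, setB) {
  key <- function(cl, d) (cl$pixels[, 2L] - 1L) * d + cl$pixels[, 1L]
  out <- list()
  for (a in setA$clusters) for (b in setB$clusters) {
    shared <- length(intersect(key(a, setA$dim[1L]), key(b, setB$dim[1L])))
    if (shared > 0L)
      out[[length(out) + 1L]] <- data.frame(idA = a$cluster_id,
                                            idB = b$cluster_id,
                                            shared_px = shared)
  }
  if (!length(out)) return(data.frame(idA = integer(), idB = integer(),
                                      shared_px = integer()))
  o <- do.call(rbind, out)
  o[order(o$idA, o$idB), ]
}

# textbook pooled two-sample t
t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# wrap a plain matrix as a rendered image on a given grid
fake_image <- function(grid, pixel_size = 20, origin = c(0, 0),
                       channel_id = "ch", nucleus_id = "nucleus") {
  structure(list(grid = grid, pixel_size = pixel_size, origin = origin,
                 channel_id = channel_id, nucleus_id = nucleus_id),
            class = "rendered_image")
}

# build a cluster_set directly from a list of pixel-index matrices
fake_set <- function(pixel_lists, dims = c(30L, 30L), pixel_size = 20,
                     origin = c(0, 0), values = NULL, channel_id = "ch",
                     nucleus_id = "nucleus") {
  geom <- list(pixel_size = pixel_size, origin = origin, dim = dims)
  clusters <- lapply(seq_along(pixel_lists), function(k) {
    ij <- pixel_lists[[k]]
    v <- if (is.null(values)) rep(1, nrow(ij)) else values[[k]]
    srfoci:::make_cluster(k, ij, v, geom)
  })
  structure(c(list(clusters = clusters), geom,
              list(channel_id = channel_id, nucleus_id = nucleus_id,
                   threshold_used = 1, min_area_used = 1L)),
            class = "cluster_set")
}

# a random small cluster set on a given grid (disjoint blobs)
random_set <- function(n_clusters, dims = c(30L, 30L), pixel_size = 20,
                       max_blob = 6L) {
  taken <- matrix(FALSE, dims[1L], dims[2L])
  pl <- list()
  while (length(pl) < n_clusters) {
    i0 <- sample.int(dims[1L] - 3L, 1L)
    j0 <- sample.int(dims[2L] - 3L, 1L)
    sz <- sample.int(max_blob, 1L)
    ij <- unique(cbind(pmin(dims[1L], i0 + sample.int(3L, sz, TRUE) - 1L),
                       pmin(dims[2L], j0 + sample.int(3L, sz, TRUE) - 1L)))
    if (!any(taken[ij])) {
      taken[ij] <- TRUE
      pl[[length(pl) + 1L]] <- ij
    }
  }
  fake_set(pl, dims = dims, pixel_size = pixel_size)
}

unit_square_roi <- function(side_nm, nucleus_id = "nucleus") {
  roi_polygon(cbind(c(0, side_nm, side_nm, 0), c(0, 0, side_nm, side_nm)),
              nucleus_id = nucleus_id)
}
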