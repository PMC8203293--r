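# Ridge-based fiber tracing: smooth -> threshold -> thin to a skeleton ->
# split at branch points -> order each chain into a path; width from the
# Euclidean distance transform sampled along the skeleton.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  keep_r <- rs + dr >= 1L & rs + dr <= nr
  keep_c <- cs + dc >= 1L & cs + dc <= nc
  out[rs[keep_r], cs[keep_c]] <- m[rs[keep_r] + dr, cs[keep_c] + dc]
  out
}

# 8-neighbour offsets in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW);
# rows are y, columns x.
zs_offsets <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                    dc = c(0, 1, 1, 1, 0, -1, -1, -1))

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels of a binary foreground until a
#' one-pixel-wide, 8-connected skeleton remains, preserving endpoints and
#' connectivity.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @return Logical matrix of the skeleton.
#' @export
thin_binary <- function(mask) {
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- lapply(seq_len(8), function(k) {
        shift_mat(img, zs_offsets[k, 1], zs_offsets[k, 2])
      })
      B <- Reduce(`+`, p)
      A <- matrix(0L, nrow(img), ncol(img))
      for (k in seq_len(8)) {
        nxt <- if (k == 8L) 1L else k + 1L
        A <- A + (p[[k]] == 0L & p[[nxt]] == 1L)
      }
      if (step == 1L) {
        kill <- img == 1L & B >= 2L & B <= 6L & A == 1L &
          p[[1]] * p[[3]] * p[[5]] == 0L & p[[3]] * p[[5]] * p[[7]] == 0L
      } else {
        kill <- img == 1L & B >= 2L & B <= 6L & A == 1L &
          p[[1]] * p[[3]] * p[[7]] == 0L & p[[1]] * p[[5]] * p[[7]] == 0L
      }
      if (any(kill)) {
        img[kill] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  thin_finalize(img == 1L)
}

# 8-adjacency between positions of the 3x3 ring (used by the simple-point test)
ring_adjacency <- local({
  adj <- matrix(FALSE, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    if (a != b) {
      adj[a, b] <- max(abs(zs_offsets[a, 1] - zs_offsets[b, 1]),
                       abs(zs_offsets[a, 2] - zs_offsets[b, 2])) <= 1
    }
  }
  adj
})

# Parallel Zhang-Suen leaves two-pixel-wide diagonal staircases invariant.
# This sequential pass deletes redundant pixels: boundary pixels with >= 2
# foreground neighbours whose neighbours form a single 8-connected component
# in the punctured 3x3 ring (so deletion cannot disconnect the skeleton).
thin_finalize <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  repeat {
    removed <- FALSE
    px <- which(skel, arr.ind = TRUE)
    for (i in seq_len(nrow(px))) {
      r <- px[i, 1]; c <- px[i, 2]
      if (!skel[r, c]) next
      ring <- logical(8)
      four_bg <- FALSE
      for (k in 1:8) {
        rr <- r + zs_offsets[k, 1]; cc <- c + zs_offsets[k, 2]
        on <- rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && skel[rr, cc]
        ring[k] <- on
        if (!on && k %in% c(1L, 3L, 5L, 7L)) four_bg <- TRUE
      }
      B <- sum(ring)
      if (B < 3L || !four_bg) next
      idx <- which(ring)
      # count 8-connected components among foreground ring cells
      seen <- logical(length(idx))
      comp <- 0L
      for (s in seq_along(idx)) {
        if (seen[s]) next
        comp <- comp + 1L
        stack <- s
        while (length(stack)) {
          cur <- stack[length(stack)]; stack <- stack[-length(stack)]
          if (seen[cur]) next
          seen[cur] <- TRUE
          stack <- c(stack, which(!seen & ring_adjacency[idx[cur], idx]))
        }
      }
      if (comp == 1L) {
        skel[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

neighbour_count <- function(skel) {
  s <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  Reduce(`+`, lapply(seq_len(8), function(k) {
    shift_mat(s, zs_offsets[k, 1], zs_offsets[k, 2])
  }))
}

# Order the pixels of a branch-free skeleton into chains. Returns a list of
# n x 2 matrices of (row, col) indices. Ties (a pixel with two onward
# neighbours, which can occur at staircase corners) are broken by the
# straightest continuation.
extract_chains <- function(skel) {
  nr <- nrow(skel)
  cnt <- neighbour_count(skel)
  avail <- skel
  chains <- list()
  walk_from <- function(r0, c0) {
    path <- matrix(NA_integer_, sum(avail), 2)
    path[1, ] <- c(r0, c0)
    avail[r0, c0] <<- FALSE
    len <- 1L
    repeat {
      r <- path[len, 1]; c <- path[len, 2]
      cand <- NULL
      for (k in seq_len(8)) {
        rr <- r + zs_offsets[k, 1]; cc <- c + zs_offsets[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(skel) && avail[rr, cc]) {
          cand <- rbind(cand, c(rr, cc))
        }
      }
      if (is.null(cand)) break
      if (nrow(cand) > 1L && len > 1L) {
        prev <- path[len, ] - path[len - 1L, ]
        turn <- apply(cand, 1, function(q) {
          step <- q - path[len, ]
          -sum(step * prev) / sqrt(sum(step^2))
        })
        cand <- cand[order(turn), , drop = FALSE]
      }
      len <- len + 1L
      path[len, ] <- cand[1, ]
      avail[cand[1, 1], cand[1, 2]] <<- FALSE
    }
    path[seq_len(len), , drop = FALSE]
  }
  endpoints <- which(skel & cnt == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(endpoints))) {
    r <- endpoints[i, 1]; c <- endpoints[i, 2]
    if (avail[r, c]) chains[[length(chains) + 1L]] <- walk_from(r, c)
  }
  remaining <- which(avail, arr.ind = TRUE) # loops
  while (nrow(remaining) > 0L) {
    chains[[length(chains) + 1L]] <- walk_from(remaining[1, 1], remaining[1, 2])
    remaining <- which(avail, arr.ind = TRUE)
  }
  chains
}

# Remove short terminal spurs (thinning artefacts at fiber caps): walk from
# each endpoint towards the first junction; if the walk is shorter than
# `max_spur_px` the branch is deleted. Single pass over the original
# endpoints only -- iterating would cascade along chains whose junction
# artefacts repeat at short intervals and erode genuine fibers.
prune_skeleton <- function(skel, max_spur_px) {
  nr <- nrow(skel); nc <- ncol(skel)
  {
    cnt <- neighbour_count(skel)
    endpoints <- which(skel & cnt == 1L, arr.ind = TRUE)
    for (i in seq_len(nrow(endpoints))) {
      r <- endpoints[i, 1]; c <- endpoints[i, 2]
      if (!skel[r, c]) next
      walk <- matrix(c(r, c), 1)
      hit_junction <- FALSE
      while (nrow(walk) <= max_spur_px) {
        cur <- walk[nrow(walk), ]
        nxt <- NULL
        for (k in seq_len(8)) {
          rr <- cur[1] + zs_offsets[k, 1]; cc <- cur[2] + zs_offsets[k, 2]
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (!skel[rr, cc]) next
          if (any(walk[, 1] == rr & walk[, 2] == cc)) next
          nxt <- rbind(nxt, c(rr, cc))
        }
        if (is.null(nxt)) break
        if (nrow(nxt) > 1L || cnt[nxt[1, 1], nxt[1, 2]] >= 3L) {
          hit_junction <- TRUE
          break
        }
        walk <- rbind(walk, nxt[1, ])
      }
      if (hit_junction && nrow(walk) <= max_spur_px) {
        skel[walk] <- FALSE
      }
    }
  }
  skel
}

# Reconnect chains across junctions by straightest continuation. Chain ends
# closer than `gap_max_px` whose outward directions oppose are merged,
# provided the gap runs over skeleton pixels (a removed branch cluster), so
# two distinct fibers with nearby tips are never joined. `skel` is the full
# skeleton before branch-point removal.
merge_chains_at_junctions <- function(chains, skel, gap_max_px = 12) {
  chains <- chains[vapply(chains, nrow, integer(1)) >= 3L]
  if (length(chains) < 2L) return(chains)
  end_dir <- function(ch, head) {
    k <- min(5L, nrow(ch) - 1L)
    v <- if (head) ch[1, ] - ch[1L + k, ] else ch[nrow(ch), ] - ch[nrow(ch) - k, ]
    n <- sqrt(sum(v^2))
    if (n == 0) c(0, 0) else v / n
  }
  ends <- list()
  for (i in seq_along(chains)) {
    for (head in c(TRUE, FALSE)) {
      pt <- if (head) chains[[i]][1, ] else chains[[i]][nrow(chains[[i]]), ]
      ends[[length(ends) + 1L]] <- list(chain = i, head = head, pt = pt,
                                        dir = end_dir(chains[[i]], head))
    }
  }
  on_skel <- function(p) {
    r <- round(p[1]); c <- round(p[2])
    rs <- max(1, r - 1):min(nrow(skel), r + 1)
    cs <- max(1, c - 1):min(ncol(skel), c + 1)
    any(skel[rs, cs])
  }
  gap_covered <- function(a, b) {
    all(vapply(c(0.25, 0.5, 0.75), function(t) {
      on_skel(a + t * (b - a))
    }, logical(1)))
  }
  comp <- seq_along(chains) # union-find to keep merged paths acyclic
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  used <- logical(length(ends))
  merges <- list()
  repeat {
    best <- NULL; best_cos <- -0.25 # only near-straight continuations
    for (a in seq_along(ends)) {
      if (used[a]) next
      for (b in seq_along(ends)) {
        if (b <= a || used[b]) next
        ea <- ends[[a]]; eb <- ends[[b]]
        if (find(ea$chain) == find(eb$chain)) next
        g <- eb$pt - ea$pt
        d <- sqrt(sum(g^2))
        if (d > gap_max_px || d == 0) next
        if (sum(ea$dir * g) <= 0 || sum(eb$dir * g) >= 0) next
        cs <- sum(ea$dir * eb$dir)
        if (cs < best_cos && gap_covered(ea$pt, eb$pt)) {
          best_cos <- cs; best <- c(a, b)
        }
      }
    }
    if (is.null(best)) break
    ea <- ends[[best[1]]]; eb <- ends[[best[2]]]
    merges[[length(merges) + 1L]] <- list(ea, eb)
    used[best] <- TRUE
    comp[find(ea$chain)] <- find(eb$chain)
  }
  if (!length(merges)) return(chains)
  # each chain end joins at most one partner: walk the merge graph into paths
  partner <- array(0L, c(length(chains), 2)) # columns: head, tail
  pend <- function(e) if (e$head) 1L else 2L
  other <- vector("list", length(chains) * 2L)
  for (m in merges) {
    partner[m[[1]]$chain, pend(m[[1]])] <- 1L
    partner[m[[2]]$chain, pend(m[[2]])] <- 1L
    other[[(m[[1]]$chain - 1L) * 2L + pend(m[[1]])]] <- m[[2]]
    other[[(m[[2]]$chain - 1L) * 2L + pend(m[[2]])]] <- m[[1]]
  }
  used <- logical(length(chains))
  out <- list()
  orient <- function(ch, start_head) if (start_head) ch else ch[nrow(ch):1, , drop = FALSE]
  for (i in seq_along(chains)) {
    if (used[i]) next
    free_head <- partner[i, 1] == 0L
    free_tail <- partner[i, 2] == 0L
    if (!free_head && !free_tail) next # interior of a longer path, or a cycle
    start_head <- free_head
    cur <- i; cur_from_head <- start_head
    acc <- orient(chains[[i]], start_head)
    used[i] <- TRUE
    repeat {
      exit_end <- if (cur_from_head) 2L else 1L
      nxt <- other[[(cur - 1L) * 2L + exit_end]]
      if (is.null(nxt) || used[nxt$chain]) break
      cur <- nxt$chain
      cur_from_head <- nxt$head
      acc <- rbind(acc, orient(chains[[cur]], cur_from_head))
      used[cur] <- TRUE
    }
    out[[length(out) + 1L]] <- acc
  }
  for (i in seq_along(chains)) { # cycles and anything untouched
    if (!used[i]) out[[length(out) + 1L]] <- chains[[i]]
  }
  out
}

smooth_path <- function(path, window = 5L) {
  n <- nrow(path)
  if (n <= window) return(path)
  sm <- path
  half <- window %/% 2L
  for (j in 1:2) {
    cs <- cumsum(c(0, path[, j]))
    i <- (half + 1L):(n - half)
    sm[i, j] <- (cs[i + half + 1L] - cs[i - half]) / window
  }
  sm
}

otsu_cut <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) abort("Degenerate intensity histogram: cannot threshold.")
  scaled <- (values - rng[1]) / (rng[2] - rng[1])
  cut <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1L)), range = c(0, 1))
  cut * (rng[2] - rng[1]) + rng[1]
}

# Returns indices of paths to keep: when most of a shorter path lies within
# the combined half-widths of a longer one, the shorter is a duplicate trace
# of the same fiber and is dropped.
dedupe_overlapping_paths <- function(paths, widths, min_overlap = 0.5) {
  arc <- vapply(paths, path_arc_length, numeric(1))
  ord <- order(arc, decreasing = TRUE)
  kept <- integer(0)
  pt_to_path_dist <- function(pts, path) {
    d <- rep(Inf, nrow(pts))
    for (i in seq_len(nrow(path) - 1L)) {
      a <- path[i, ]; b <- path[i + 1L, ]
      ab <- b - a; len2 <- sum(ab^2)
      t <- if (len2 == 0) rep(0, nrow(pts)) else {
        pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2, 0), 1)
      }
      d <- pmin(d, sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 +
                          (pts[, 2] - (a[2] + t * ab[2]))^2))
    }
    d
  }
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      tol <- (widths[i] + widths[j]) / 2
      frac <- mean(pt_to_path_dist(paths[[i]], paths[[j]]) <= tol)
      if (frac > min_overlap) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  sort(kept)
}

# Geometric fallback for components whose skeleton collapsed during thinning
# (parallel thinning can erode most of a band near 45 degrees): project the
# component's pixels onto their principal axis and take the mean transverse
# position per longitudinal bin, giving a ridge polyline in (row, col).
component_axis_path <- function(px_rc, bin_px = 2) {
  xy <- cbind(px_rc[, 2], px_rc[, 1]) # (x, y)
  ctr <- colMeans(xy)
  centred <- sweep(xy, 2, ctr)
  e <- eigen(crossprod(centred) / nrow(xy), symmetric = TRUE)
  u <- e$vectors[, 1]; v <- e$vectors[, 2]
  t <- centred %*% u
  s <- centred %*% v
  bins <- floor((t - min(t)) / bin_px)
  path <- NULL
  for (b in sort(unique(bins))) {
    sel <- bins == b
    pt <- ctr + mean(t[sel]) * u + mean(s[sel]) * v
    path <- rbind(path, c(pt[2], pt[1])) # back to (row, col)
  }
  path
}

#' Trace collagen fibers in an SHG image
#'
#' Extracts individual fibers from an SHG-like image and measures each one.
#' The tracer Gaussian-smooths the image, thresholds it (Otsu over nonzero
#' pixels by default), removes small specks, thins the foreground to a
#' skeleton, splits the skeleton at branch points, and orders each branch-free
#' chain into a path. Fiber width is estimated perpendicular to the local path
#' direction as twice the distance-transform value sampled along the interior
#' of the skeleton (end pixels, where the distance transform is dominated by
#' the fiber cap, are trimmed); fiber length is the arc length of the
#' lightly smoothed skeleton path. Fibers shorter than `min_length_um` are
#' discarded.
#'
#' @param image An [shg_image()].
#' @param min_length_um Minimum fiber arc length to keep, um.
#' @param intensity_threshold Fixed threshold; `NULL` (default) uses Otsu over
#'   nonzero pixels of the smoothed image.
#' @param smooth_um Gaussian smoothing scale before thresholding, um.
#' @param source_id Identifier recorded on the returned set.
#' @return A [fiber_set()]; empty for a blank image.
#' @export
trace_fibers <- function(image, min_length_um = 20, intensity_threshold = NULL,
                         smooth_um = 0.5, source_id = NA_character_) {
  stopifnot(inherits(image, "shg_image"))
  px <- image$pixel_size_um
  x <- image$intensity
  if (all(x == 0)) return(fiber_set(source_id = source_id))
  sigma_px <- smooth_um / px
  sm <- if (sigma_px >= 0.5) {
    EBImage::imageData(EBImage::gblur(EBImage::Image(x / max(x)), sigma = sigma_px)) * max(x)
  } else {
    x
  }
  thr <- if (is.null(intensity_threshold)) otsu_cut(sm[sm > 0]) else intensity_threshold
  mask <- sm > thr
  if (!any(mask)) return(fiber_set(source_id = source_id))
  # drop specks smaller than a minimal fiber footprint
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab[lab > 0])
  min_px <- max(5L, floor(min_length_um / px / 2))
  keep <- which(sizes >= min_px)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  if (!any(mask)) return(fiber_set(source_id = source_id))

  skel <- thin_binary(mask)
  dm0 <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  half_w_px <- stats::median(dm0[skel])
  skel <- prune_skeleton(skel, max_spur_px = ceiling(2 * half_w_px) + 3L)
  cnt <- neighbour_count(skel)
  simple <- skel & cnt <= 2L       # remove branch points -> simple chains
  dm <- dm0
  chains <- extract_chains(simple)
  chains <- merge_chains_at_junctions(chains, skel)

  # components whose chains cover far less centerline than area/width implies
  # lost their skeleton to thinning erosion; rebuild those paths geometrically
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  chain_comp <- vapply(chains, function(ch) lab[ch[1, 1], ch[1, 2]], numeric(1))
  for (cmp in setdiff(unique(as.vector(lab)), 0)) {
    sel <- which(chain_comp == cmp)
    covered <- sum(vapply(chains[sel], nrow, integer(1)))
    comp_px <- which(lab == cmp, arr.ind = TRUE)
    w_px <- max(2 * stats::quantile(dm[comp_px], 0.9), 2)
    expected <- nrow(comp_px) / w_px
    if (covered < 0.6 * expected && expected > 4) {
      if (length(sel)) {
        chains[sel] <- NULL
        chain_comp <- chain_comp[-sel]
      }
      chains[[length(chains) + 1L]] <- component_axis_path(comp_px)
      chain_comp <- c(chain_comp, cmp)
    }
  }

  # thinning retracts chain ends into the fiber (strongly so for bands near
  # 45 degrees): walk from each end along the local tangent to the mask
  # boundary and restore the retraction beyond the rounded cap (half-width)
  extend_end <- function(sp, head, half_width_px) {
    n <- nrow(sp)
    k <- min(5L, n - 1L)
    pt <- if (head) sp[1, ] else sp[n, ]
    v <- if (head) sp[1, ] - sp[1L + k, ] else sp[n, ] - sp[n - k, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NULL)
    v <- v / nv
    t <- 0
    repeat {
      nt <- t + 0.25
      p <- pt + nt * v
      r <- round(p[1]); c <- round(p[2])
      if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask) || !mask[r, c]) break
      t <- nt
    }
    add <- t - half_width_px
    if (add > 0.25) pt + add * v else NULL
  }
  paths_um <- list(); widths <- c()
  for (ch in chains) {
    if (nrow(ch) < 4L) next
    ri <- pmin(pmax(round(ch[, 1]), 1), nrow(dm))
    ci <- pmin(pmax(round(ch[, 2]), 1), ncol(dm))
    d <- dm[cbind(ri, ci)]
    trim <- max(2L, ceiling(stats::median(d)))
    core <- if (nrow(ch) > 2L * trim + 2L) d[(trim + 1L):(nrow(ch) - trim)] else d
    # the distance transform at the ridge reads half-width plus about half a
    # pixel of discretisation offset
    width_um <- max(2 * mean(core) - 0.25, 1) * px
    sp <- smooth_path(ch)
    ext_head <- extend_end(sp, TRUE, width_um / 2 / px)
    ext_tail <- extend_end(sp, FALSE, width_um / 2 / px)
    if (!is.null(ext_head)) sp <- rbind(ext_head, sp)
    if (!is.null(ext_tail)) sp <- rbind(sp, ext_tail)
    # path in um, (x, y) = (col, row)
    p_um <- cbind(sp[, 2], sp[, 1]) * px
    arc <- path_arc_length(p_um)
    if (arc < min_length_um) next
    attr(p_um, "arc_length_um") <- arc
    paths_um[[length(paths_um) + 1L]] <- p_um
    widths <- c(widths, width_um)
  }
  if (length(paths_um) == 0L) return(fiber_set(source_id = source_id))
  # suppress duplicates: thinning can leave a closed double line along one
  # fiber, yielding two chains tracing the same structure
  if (length(paths_um) > 1L) {
    keep <- dedupe_overlapping_paths(paths_um, widths)
    paths_um <- paths_um[keep]
    widths <- widths[keep]
  }
  fs <- fiber_set(paths_um, width_um = widths, source_id = source_id)
  fs$length_um <- map_dbl(paths_um, function(p) attr(p, "arc_length_um"))
  fs
}
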