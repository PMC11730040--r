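# shared fixture builders and independent oracles

# binary volume from a coordinate matrix
mk_mask <- function(coords, dm = c(10, 10, 10), vd = c(1, 1, 1), affine = NULL) {
  m <- array(0L, dm)
  if (!is.null(coords) && nrow(coords)) {
    m[(coords[, 3] - 1) * dm[1] * dm[2] + (coords[, 2] - 1) * dm[1] + coords[, 1]] <- 1L
  }
  cmb_volume(m, vd, affine, dtype = "binary")
}

# digitised ball mask (mm-space inclusion), matching the phantom renderer
mk_ball_mask <- function(centre, radius_mm, dm = c(20, 20, 20), vd = c(1, 1, 1)) {
  idx <- arrayInd(seq_len(prod(dm)), dm)
  d <- sweep(sweep(idx, 2, centre), 2, vd, `*`)
  mk_mask(idx[sqrt(rowSums(d^2)) <= radius_mm + 1e-9, , drop = FALSE], dm, vd)
}

# independent connected-components oracle: BFS flood fill over a coordinate list
flood_fill_components <- function(mask_arr, connectivity = 26) {
  dm <- dim(mask_arr)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1), ,
             drop = FALSE]
  fg <- which(mask_arr == 1)
  seen <- logical(length(fg))
  coords <- arrayInd(fg, dm)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  comps <- list()
  for (s in seq_along(fg)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- integer()
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      nb <- sweep(off, 2, -coords[cur, ])
      hits <- match(paste(nb[, 1], nb[, 2], nb[, 3]), key)
      hits <- hits[!is.na(hits) & !seen[hits]]
      seen[hits] <- TRUE
      queue <- c(queue, hits)
    }
    comps[[length(comps) + 1]] <- coords[sort(members), , drop = FALSE]
  }
  comps
}

# all permutations of 1..n (n <= 7)
perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n))[-k][sub], nrow(sub)))
  }))
}

# exhaustive optimal one-to-one matching by (count, total overlap);
# overlap matrix rows = pred, cols = ref
brute_force_match <- function(ov) {
  np <- nrow(ov); nr <- ncol(ov); n <- max(np, nr)
  pad <- matrix(0, n, n)
  pad[seq_len(np), seq_len(nr)] <- ov
  best <- NULL; best_score <- c(-1, -1)
  pm <- perms(n)
  for (r in seq_len(nrow(pm))) {
    sel <- cbind(seq_len(n), pm[r, ])
    ovs <- pad[sel]
    cnt <- sum(ovs >= 1); tot <- sum(ovs[ovs >= 1])
    if (cnt > best_score[1] || (cnt == best_score[1] && tot > best_score[2])) {
      best_score <- c(cnt, tot)
      keep <- ovs >= 1 & sel[, 1] <= np & sel[, 2] <= nr
      best <- sel[keep, , drop = FALSE]
    }
  }
  list(pairs = best[order(best[, 1]), , drop = FALSE], score = best_score)
}

# small synthetic two-structure atlas: structure A fills i <= split,
# structure B fills i > split (full j, k extent)
mk_two_block_atlas <- function(dm = c(10, 10, 10), split = 5, vd = c(1, 1, 1),
                               names = c("thalamus", "frontal")) {
  lut <- mars_lut()
  lab <- array(0L, dm)
  codes <- lut$code[match(names, lut$name)]
  lab[1:split, , ] <- codes[1]
  lab[(split + 1):dm[1], , ] <- codes[2]
  mars_atlas(cmb_volume(lab, vd, dtype = "label"), lut = lut, space = "subject")
}

# assignments tibble shortcut for evaluation tests
mk_assignments <- function(status, pred_region, ref_region) {
  tibble::tibble(status = status, pred_region = pred_region, ref_region = ref_region)
}
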