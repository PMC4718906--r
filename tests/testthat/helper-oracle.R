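# Independent brute-force flood-fill focus counter, kept deliberately
# separate from the package's labelling path: plain R, queue-based BFS over
# an explicit neighbour list.
oracle_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  manh <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- manh > 0 & switch(as.character(connectivity),
                            "6" = manh <= 1,
                            "18" = manh <= 2,
                            "26" = rep(TRUE, nrow(off)))
  as.matrix(off[keep, ])
}

oracle_count_foci <- function(vol, voi, thr, connectivity = 26, min_size = 1) {
  d <- dim(vol)
  fg <- voi & (vol >= thr)
  seen <- array(FALSE, d)
  off <- oracle_offsets(connectivity)
  count <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!fg[i, j, k] || seen[i, j, k]) next
    queue <- matrix(c(i, j, k), ncol = 3)
    seen[i, j, k] <- TRUE
    size <- 0
    while (nrow(queue) > 0) {
      v <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1
      for (r in seq_len(nrow(off))) {
        w <- v + off[r, ]
        if (any(w < 1) || any(w > d)) next
        if (fg[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue <- rbind(queue, w)
        }
      }
    }
    if (size >= min_size) count <- count + 1
  }
  count
}
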