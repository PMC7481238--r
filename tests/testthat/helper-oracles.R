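# Independent reference implementations and small constructors used across
# the suite. The oracles are deliberately naive (double loops, BFS) and
# share no code with the package internals they check.

# reference majority filter: per-pixel count over the valid 8-neighbourhood
brute_majority <- function(m, exclude = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    centre <- m[r, c]
    if (centre %in% exclude) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      v <- m[rr, cc]
      if (!v %in% exclude) nb <- c(nb, v)
    }
    if (length(nb) == 0) next
    tab <- table(nb)
    cand <- as.integer(names(tab))
    cnt <- as.integer(tab)
    keep <- cand != centre
    cand <- cand[keep]; cnt <- cnt[keep]
    if (length(cand) == 0) next
    thr <- ceiling(length(nb) / 2)
    ok <- cnt >= thr & cnt == max(cnt)
    if (any(ok)) out[r, c] <- min(cand[ok])
  }
  out
}

# reference connected-component labeling by BFS
flood_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(NA_integer_, nr, nc)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nxt <- 0L
  for (start in which(!is.na(m) & m != 0L)) {
    if (!is.na(lab[start])) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- (cc - 1) * nr + rr
        if (is.na(lab[j]) && !is.na(m[j]) && m[j] != 0L && m[j] == m[i]) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# binary stack [n_pixels x 1 x n_years] from per-pixel year sequences
bin_stack <- function(seqs, years = 2008:(2007 + length(seqs[[1]]))) {
  m <- do.call(rbind, seqs)
  arr <- array(as.integer(m), dim = c(nrow(m), 1L, ncol(m)))
  attr(arr, "years") <- as.integer(years)
  arr
}

# epoch stack with the same pixel layout
epoch_stack <- function(seqs, years) {
  bin_stack(seqs, years)
}

# land_series from per-pixel legend-code sequences (rows = pixels)
series_from_codes <- function(code_mat, years = 2008:(2007 + ncol(code_mat)),
                              legend = default_legend(), pixel_size_m = 30) {
  rasters <- lapply(seq_len(ncol(code_mat)), function(k) {
    matrix(as.integer(code_mat[, k]), nrow(code_mat), 1L)
  })
  land_series(rasters, years, legend, pixel_size_m)
}

# bare transition_map for accounting tests
make_tmap <- function(transition, conv_year = NULL, pre_cover = NULL,
                      post_cover = NULL, years = 2008:2017,
                      legend = default_legend(), pixel_size_m = 30) {
  d <- dim(transition)
  blank <- matrix(NA_integer_, d[1], d[2])
  structure(
    list(transition = transition,
         conv_year = conv_year %||% blank,
         pre_cover = pre_cover %||% blank,
         post_cover = post_cover %||% blank,
         years = as.integer(years), legend = legend,
         pixel_size_m = pixel_size_m, conv_index = NULL,
         qa_single_epoch = NULL),
    class = "transition_map"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

code_of <- function(name, legend = default_legend()) {
  legend$code[match(name, legend$name)]
}

# full detection pipeline on a synthetic scene
detect <- function(scene, mmu_acres = 5, passes = 1) {
  reclassify_binary(scene$series) |>
    encode_trajectories() |>
    majority_filter(passes = passes) |>
    classify_transitions(scene$epochs) |>
    attribute_conversion(scene$series) |>
    apply_refinements(quiet = TRUE) |>
    enforce_mmu(pixel_threshold(mmu_acres, scene$series$pixel_size_m))
}

agreement <- function(a, b) {
  mean((a == b) | (is.na(a) & is.na(b)), na.rm = FALSE)
}

legend_group_lookup_test <- function(legend) {
  setNames(ifelse(legend$group == "crop", 1L,
                  ifelse(legend$group == "noncrop", 0L, 2L)),
           legend$code)
}
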