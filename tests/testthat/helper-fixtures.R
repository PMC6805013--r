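# fixtures built in code: small images, masks, and movies

# binary disk in an H x W frame, centre (cr, cc) in 1-based pixel units
disk_mask <- function(H, W, cr, cc, radius) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= radius^2
}

# movie with one disk per frame following a path of centres (n x 2, row/col)
disk_movie <- function(path, H = 64, W = 64, radius = 10, pixel_size = 0.5,
                       frame_interval = 15, fg = 200, bg = 100) {
  Tn <- nrow(path)
  arr <- array(bg, c(H, W, Tn))
  for (t in seq_len(Tn)) {
    arr[, , t][disk_mask(H, W, path[t, 1], path[t, 2], radius)] <- fg
  }
  cell_movie(list(nuclei = arr), pixel_size, frame_interval)
}

# mask stack from a list of logical frames
stack_from <- function(frames, pixel_size = 0.5, frame_interval = 1) {
  labs <- vapply(frames, function(f) {
    as.matrix(EBImage::bwlabel(f * 1L))
  }, matrix(0, nrow(frames[[1]]), ncol(frames[[1]])))
  mask_stack(array(as.integer(labs), dim = c(dim(frames[[1]]), length(frames))),
    provenance = "fixture",
    pixel_size = pixel_size, frame_interval = frame_interval
  )
}

# exhaustive-search oracle for circular index alignment
align_shift_oracle <- function(prev, cur) {
  P <- nrow(prev)
  ss <- vapply(0:(P - 1), function(k) {
    idx <- ((seq_len(P) - 1 + k) %% P) + 1
    sum((prev - cur[idx, ])^2)
  }, numeric(1))
  k_all <- 0:(P - 1)
  k_signed <- ifelse(k_all > P / 2, k_all - P, k_all)
  best <- min(ss)
  cand <- which(ss <= best + 1e-9)
  cand <- cand[order(abs(k_signed[cand]), k_signed[cand])]
  k_signed[cand[1]]
}
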