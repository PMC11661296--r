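# Shared fixtures for the test suite: small phantom scenes and utilities.

iou <- function(a, b) sum(a & b) / sum(a | b)

# best IoU of ground-truth object i against any segmented label
best_iou <- function(labels, truth, i) {
  n <- max(labels)
  if (n == 0L) return(0)
  max(vapply(seq_len(n), function(j) iou(labels == j, truth == i), numeric(1)))
}

# a small, quickly rendered single-nucleus ramp scene (ratio 1 -> 3)
ramp_scene <- function(acq, n_frames = 10, img_px = c(160, 160)) {
  ph <- nucleus_phantom(
    center_um = c(12.8, 12.8, 6), semi_um = c(6, 6, 3),
    rim_intensity = seq(150, 450, length.out = n_frames),
    interior_intensity = 150
  )
  make_nucleus_timelapse(ph, n_frames = n_frames, acq = acq,
                         img_px = img_px, n_z = 9)
}

# segment every frame of a scene with default parameters
segment_scene <- function(scene) {
  pp <- preprocess_nuclei(scene$stack)
  lapply(seq_len(dim(scene$stack$data)[1]), function(t) {
    segment_nuclei(pp, t = t)
  })
}

# hand-built label volume: one cube object centred at (cy, cx)
cube_labels <- function(cy, cx, dim_yx = c(256, 300), half = 10) {
  a <- array(0L, c(dim_yx[1], dim_yx[2], 3))
  a[(cy - half):(cy + half), (cx - half):(cx + half), 2] <- 1L
  a
}

# discretized disc mask
disc_mask <- function(r, n = 2 * r + 21) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(y, x) (y - ctr)^2 + (x - ctr)^2 <= r^2)
}

# independent Welch t-test oracle: direct evaluation of the formula
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
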