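# Shared fixtures, all generated in code.

# Solid-colour image: every pixel (r, g, b).
flat_rgb <- function(h, w, r, g, b) {
  a <- array(0, dim = c(h, w, 3))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  a
}

square_mask <- function(side, h, w, r0 = 1L, c0 = 1L) {
  m <- matrix(0L, side, side)
  m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
  m
}

# An RGB image from an HSV spec applied to a mask's foreground.
hsv_image <- function(mask, hue_deg, s = 0.8, v = 0.8) {
  col <- grDevices::col2rgb(grDevices::hsv(hue_deg / 360, s, v))[, 1] / 255
  a <- array(0, dim = c(nrow(mask), ncol(mask), 3))
  for (ch in 1:3) {
    pl <- a[, , ch]
    pl[mask > 0] <- col[ch]
    a[, , ch] <- pl
  }
  a
}

# Small cached synthetic manifest shared by preprocessing/eval tests.
tiny_records <- synth_dataset(24, seed = 301)
tiny_manifest <- build_dataset(tiny_records, target_resolution = 64,
                               test_fraction = 0.25, seed = 302)
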