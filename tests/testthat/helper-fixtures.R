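# Shared fixtures built in code.

# The reference disk phantom: bright disk r = 25 on a dark background.
disk_phantom <- function(shape = c(128, 128), fg = 220, bg = 30, r = 25,
                         noise_sigma = 0, seed = NULL) {
  make_phantom(shape = shape, background = bg,
               blobs = list(list(center = (shape + 1) / 2, radius = r,
                                 intensity = fg)),
               noise_sigma = noise_sigma, seed = seed)
}

# Closed circular polygon in (row, col) coordinates, first vertex repeated.
circle_contour <- function(center, radius, id = NULL, iteration = NA,
                           n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  v <- cbind(row = center[1] + radius * cos(th),
             col = center[2] + radius * sin(th))
  list(id = id, vertices = v, iteration = iteration,
       area = spfseg:::polygon_area(v))
}

# A contour map realizing the schematic ten-contour inclusion topology:
# C1 -> {C2, C3}; C2 -> C4 -> C5; C3 -> {C6, C7}; C6 -> C8 -> C9;
# C7 -> C10.
schematic_contours <- function() {
  specs <- list(
    C1  = list(c(0, 0), 60),
    C2  = list(c(0, -28), 24),
    C3  = list(c(0, 28), 26),
    C4  = list(c(0, -28), 17),
    C5  = list(c(0, -28), 10),
    C6  = list(c(-13, 28), 11),
    C7  = list(c(14, 28), 11),
    C8  = list(c(-13, 28), 7),
    C9  = list(c(-13, 28), 3),
    C10 = list(c(14, 28), 6)
  )
  mapply(function(s, id) circle_contour(s[[1]], s[[2]], id = id),
         specs, names(specs), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
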