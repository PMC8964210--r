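# Fixtures built in code: hand-countable cells, rasterized disks, textures.

# 30x30 gray image: 10x10 nucleus (rows/cols 11:20) at gray 100, 300-px
# cytoplasm strip (rows 1:10) at gray 180. All 13 morphometrics are
# hand-countable: A_n = 100, L = W = 10, P_n = 36, cell_area = 400.
square_cell_gray <- function() {
  gray <- matrix(0, 30, 30)
  nucleus <- matrix(FALSE, 30, 30); nucleus[11:20, 11:20] <- TRUE
  cytoplasm <- matrix(FALSE, 30, 30); cytoplasm[1:10, ] <- TRUE
  gray[nucleus] <- 100
  gray[cytoplasm] <- 180
  list(gray = gray, nucleus = nucleus, cytoplasm = cytoplasm)
}

# logical disk mask: pixel centers within radius r of the matrix center
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= r^2
}

# independent pixel-enumeration oracle for disk area and boundary count
disk_oracle <- function(r) {
  xs <- seq(-ceiling(r) - 2, ceiling(r) + 2)
  g <- expand.grid(x = xs, y = xs)
  inside <- g$x^2 + g$y^2 <= r^2
  key <- function(x, y) paste(x, y)
  in_set <- new.env(parent = emptyenv())
  for (i in which(inside)) assign(key(g$x[i], g$y[i]), TRUE, in_set)
  has <- function(x, y) !is.null(in_set[[key(x, y)]])
  boundary <- 0
  for (i in which(inside)) {
    x <- g$x[i]; y <- g$y[i]
    if (!(has(x - 1, y) && has(x + 1, y) && has(x, y - 1) && has(x, y + 1)))
      boundary <- boundary + 1
  }
  list(area = sum(inside), perimeter = boundary)
}

# rotate a matrix by 90 degrees (counter-clockwise)
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# anisotropic seeded texture on an n x n frame
seeded_texture <- function(n = 64, seed = 7) {
  set.seed(seed)
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  round(128 + 45 * sin(0.55 * cc + 0.1 * rr) +
          matrix(rnorm(n * n, 0, 6), n, n))
}

# wrap a gray matrix + masks into a cell_image (gray replicated to RGB)
as_cell_image <- function(gray, nucleus, cytoplasm, label = "columnar",
                          image_id = "fixture") {
  structure(list(pixels = array(rep(gray, 3), c(dim(gray), 3)),
                 nucleus_mask = nucleus, cytoplasm_mask = cytoplasm,
                 label = label, image_id = image_id),
            class = "cell_image")
}

# run expr under a fixed seed (tests only)
with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}
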