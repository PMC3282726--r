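# Shared fixture builders: everything is generated in code at test time.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a small FASTA file and return its path
write_tmp_fasta <- function(entries, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- character(0)
  for (h in names(entries)) {
    body <- entries[[h]]
    if (!is.null(wrap)) {
      body <- vapply(seq(1, nchar(body), wrap), function(i)
        substr(body, i, i + wrap - 1), character(1))
    }
    lines <- c(lines, paste0(">", h), body)
  }
  writeLines(lines, path)
  path
}

# trapezoid-rule oracle for the DV S/L descriptor: numerically integrate |y|
# over a fine grid (|y| is piecewise linear between integer x), divide by the
# summed segment lengths
sl_oracle <- function(curve) {
  f <- stats::approxfun(curve$x, curve$y)
  grid <- seq(0, max(curve$x), by = 1 / 64)
  vals <- abs(f(grid))
  s <- sum((vals[-1] + vals[-length(vals)]) / 2) / 64
  l <- sum(sqrt(diff(curve$x)^2 + diff(curve$y)^2))
  s / l
}

# brute-force Wilson interval: invert the score test by solving the quadratic
# (1 + z^2/n) p^2 - (2 phat + z^2/n) p + phat^2 = 0 with polyroot
wilson_oracle <- function(k, n, gamma = 0.95) {
  z <- qnorm((1 + gamma) / 2)
  phat <- k / n
  roots <- sort(Re(polyroot(c(phat^2, -(2 * phat + z^2 / n), 1 + z^2 / n))))
  c(lower = max(0, roots[1]), upper = min(1, roots[2]))
}

# tetrahedron containment: a point is inside iff, for every face (a triple of
# vertices), it lies on the same side of the face plane as the fourth vertex
in_tetrahedron <- function(points, tol = 1e-9) {
  v <- fj_vertices()
  ok <- rep(TRUE, nrow(points))
  for (drop in 1:4) {
    face <- v[-drop, , drop = FALSE]
    nrm <- pracma_cross(face[2, ] - face[1, ], face[3, ] - face[1, ])
    side <- sign(sum(nrm * (v[drop, ] - face[1, ])))
    proj <- as.numeric((points - matrix(face[1, ], nrow(points), 3,
                                        byrow = TRUE)) %*% nrm)
    ok <- ok & (side * proj >= -tol)
  }
  ok
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
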