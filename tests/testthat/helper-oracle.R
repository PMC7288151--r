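# Independent oracles, written before the implementations they check.

# Thin-lens chief-ray construction of the triangulation displacement.
# Reference plane z = 0, A at the origin, surface normal +z. The incident
# sheet arrives from up-right at angle alpha to the normal; the lens sits
# up-left at angle beta on the other side of the normal, distance l from A.
# The camera line passes through the image of A at angle theta to the axis.
# Returns the SIGNED position (um) of the B-spot along the camera line
# relative to the image of A, for a surface displaced by dz (dz > 0 above
# the reference plane, dz < 0 below).
oracle_raytrace_dx <- function(dz, alpha, beta, theta, f_mm, l_mm) {
  a <- alpha * pi / 180
  b <- beta * pi / 180
  th <- theta * pi / 180
  f <- f_mm * 1000
  l <- l_mm * 1000
  A <- c(0, 0)
  din <- c(-sin(a), -cos(a))            # direction of travel of incident ray
  B <- A + (-dz / cos(a)) * din         # incident ray meets plane z = dz
  v <- c(-sin(b), cos(b))               # A -> lens direction
  d <- l * f / (l - f)
  lens <- A + l * v
  A_img <- lens + d * v
  p <- c(-v[2], v[1])                   # lateral unit vector
  w <- B - lens
  s_obj <- -sum(w * v)
  h <- sum(w * p)
  s_img <- s_obj * f / (s_obj - f)
  m <- -s_img / s_obj
  B_img <- lens + s_img * v + m * h * p
  cam <- cos(th) * v + sin(th) * p      # camera line direction through A_img
  r <- B_img - lens                     # chief ray direction
  tx <- solve(cbind(r, -cam), A_img - lens)
  unname(tx[2])
}

# Brute-force per-row brightest-column scan with tie averaging, looped over
# every pixel the slow way.
oracle_contour <- function(m, min_intensity) {
  H <- nrow(m)
  pos <- rep(NA_real_, H)
  valid <- logical(H)
  for (i in seq_len(H)) {
    best <- -Inf
    js <- integer(0)
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > best) {
        best <- m[i, j]
        js <- j
      } else if (m[i, j] == best) {
        js <- c(js, j)
      }
    }
    if (best >= min_intensity) {
      valid[i] <- TRUE
      pos[i] <- mean(js)
    }
  }
  list(column_position = pos, valid = valid)
}
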