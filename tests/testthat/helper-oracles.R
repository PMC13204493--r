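# Brute-force reference implementations, written independently of the
# package internals: explicit per-pixel loops over mirror-padded windows.

pad_sym <- function(m, p) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- c(p:1, 1:n1, n1:(n1 - p + 1))
  ci <- c(p:1, 1:n2, n2:(n2 - p + 1))
  m[ri, ci]
}

oracle_local_std <- function(x, w) {
  h <- (w - 1) / 2
  xp <- pad_sym(x, h)
  out <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    win <- xp[i:(i + w - 1), j:(j + w - 1)]
    out[i, j] <- sqrt(mean((win - mean(win))^2))
  }
  out
}

oracle_template <- function(r, kind, inner) {
  tt <- seq(-r, r)
  rho <- sqrt(outer(tt^2, tt^2, "+"))
  sup <- rho <= r + 1e-9
  tv <- matrix(0, 2 * r + 1, 2 * r + 1)
  if (kind == "disc") tv[sup & rho <= 0.7 * r] <- 1
  else tv[sup & rho > inner * r] <- 1
  list(values = tv, support = sup)
}

oracle_zncc <- function(x, r, kind = "annulus", inner = 0.4) {
  tpl <- oracle_template(r, kind, inner)
  sup <- tpl$support
  t0 <- tpl$values - mean(tpl$values[sup])
  t0[!sup] <- 0
  tn <- sqrt(sum(t0^2))
  xp <- pad_sym(x, r)
  out <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    win <- xp[i:(i + 2 * r), j:(j + 2 * r)]
    wv <- win[sup]
    vw <- sum((wv - mean(wv))^2)
    out[i, j] <- if (vw < 1e-12) 0
                 else min(max(sum(win * t0) / (sqrt(vw) * tn), -1), 1)
  }
  out
}

oracle_maxima <- function(x, d) {
  n1 <- nrow(x); n2 <- ncol(x)
  cand <- list()
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (x[i, j] <= 0) next
    rr <- max(1, i - d):min(n1, i + d)
    cc <- max(1, j - d):min(n2, j + d)
    if (x[i, j] >= max(x[rr, cc]))
      cand[[length(cand) + 1]] <- c(i, j, x[i, j])
  }
  if (!length(cand))
    return(data.frame(row = integer(), col = integer(), score = numeric()))
  m <- do.call(rbind, cand)
  m <- m[order(-m[, 3], m[, 1], m[, 2]), , drop = FALSE]
  keep <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(m))) {
    acc <- which(keep)
    keep[i] <- !length(acc) ||
      all((m[acc, 1] - m[i, 1])^2 + (m[acc, 2] - m[i, 2])^2 >= d^2)
  }
  data.frame(row = as.integer(m[keep, 1]), col = as.integer(m[keep, 2]),
             score = m[keep, 3])
}

# Fraction of truth objects with a candidate center within `tol` px.
truth_recall <- function(candidates, truth, tol = 5) {
  if (nrow(truth) == 0L) return(NA_real_)
  if (length(candidates) == 0L) return(0)
  ctr <- t(vapply(candidates, function(c) c$center, c(row = 0, col = 0)))
  mean(vapply(seq_len(nrow(truth)), function(i)
    min((ctr[, 1] - truth$row[i])^2 + (ctr[, 2] - truth$col[i])^2) <= tol^2,
    TRUE))
}

# A hand-built candidate with a given mask shape on a constant crop.
make_mask_candidate <- function(mask, crop = NULL, score = 0.5) {
  if (is.null(crop)) crop <- matrix(1000, nrow(mask), ncol(mask))
  list(center = c(row = nrow(mask) / 2, col = ncol(mask) / 2),
       radius_px = sqrt(sum(mask) / pi), area_px = sum(mask),
       crop = crop, mask = mask, bbox = c(row = 1L, col = 1L),
       peak_score = score, label = NULL, features = NULL)
}

disc_mask <- function(n, r, cr = (n + 1) / 2, cc = cr) {
  rho <- sqrt(outer((1:n - cr)^2, (1:n - cc)^2, "+"))
  rho <= r
}
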