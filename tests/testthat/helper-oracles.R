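# Independent oracles and small fixture builders used across the suite.

# random symmetric positive-definite matrix
random_spd <- function(b, jitter = 0.5) {
  a <- matrix(rnorm(b * b), b)
  crossprod(a) + jitter * diag(b)
}

# AUC by exhaustive pair counting: concordant pairs count 1, ties 1/2
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# brute-force flood fill connected-component count on a 3-D binary array
flood_fill_count <- function(binary, connectivity = 26L) {
  d <- dim(binary)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  count <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!binary[i, j, k] || seen[i, j, k]) next
    count <- count + 1
    stack <- matrix(c(i, j, k), 1)
    seen[i, j, k] <- TRUE
    while (nrow(stack) > 0) {
      v <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        if (binary[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack <- rbind(stack, w)
        }
      }
    }
  }
  count
}

# dense direct evaluation of the ACE quadratic-form formula
ace_formula <- function(x, s, mu, cm_inv) {
  ds <- s - mu; dx <- x - mu
  num <- drop(t(ds) %*% cm_inv %*% dx)^2
  den <- drop(t(ds) %*% cm_inv %*% ds) * drop(t(dx) %*% cm_inv %*% dx)
  num / den
}

# digital solid ball as voxel index matrix and as binary array
digital_ball <- function(radius_vox, dim_n = 2 * radius_vox + 3) {
  ctr <- (dim_n + 1) / 2
  g <- expand.grid(x = 1:dim_n, y = 1:dim_n, z = 1:dim_n)
  inside <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= radius_vox^2
  list(vox = as.matrix(g[inside, ]),
       arr = array(inside, c(dim_n, dim_n, dim_n)))
}

# tiny two-class toy table for model-level tests
toy_feature_table <- function(n = 40, seed = 42, beta = c(-1, 2),
                              id_start = 1L) {
  set.seed(seed)
  x <- rnorm(n)
  p <- plogis(beta[1] + beta[2] * x)
  tibble::tibble(patient_id = seq(id_start, length.out = n),
                 x = x, cspca = as.integer(runif(n) < p))
}

# concatenate two 3-D arrays along the slice axis
abind_slices <- function(a, b) {
  d <- dim(a)
  out <- array(0L, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}
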