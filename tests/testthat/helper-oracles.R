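# Independent oracles used across test files. These deliberately avoid the
# package's own kernels: plain-R brute force only.

# brute-force wall shell: non-cavity voxel centers within Euclidean
# distance <= t of any cavity voxel center
oracle_wall_shell <- function(cav, spacing, thickness) {
  d <- dim(cav)
  idx_cav <- which(cav, arr.ind = TRUE)
  ctr_cav <- sweep(idx_cav - 1, 2, spacing, `*`)
  wall <- array(FALSE, d)
  idx_all <- which(!cav, arr.ind = TRUE)
  ctr_all <- sweep(idx_all - 1, 2, spacing, `*`)
  for (i in seq_len(nrow(idx_all))) {
    d2 <- colSums((t(ctr_cav) - ctr_all[i, ])^2)
    if (min(d2) <= thickness^2 + 1e-12) wall[matrix(idx_all[i, ], 1)] <- TRUE
  }
  wall
}

# plain-R 6-connected flood fill, counts components of a logical array
oracle_n_components <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  ncomp <- 0
  nb <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  todo <- which(mask & !seen, arr.ind = TRUE)
  while (nrow(todo) > 0) {
    ncomp <- ncomp + 1
    stack <- todo[1, , drop = FALSE]
    seen[stack] <- TRUE
    while (nrow(stack) > 0) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in 1:6) {
        nxt <- cur + nb[k, ]
        if (any(nxt < 1) || any(nxt > d)) next
        m <- matrix(nxt, 1)
        if (mask[m] && !seen[m]) {
          seen[m] <- TRUE
          stack <- rbind(stack, nxt)
        }
      }
    }
    todo <- which(mask & !seen, arr.ind = TRUE)
  }
  ncomp
}

# brute-force threshold power: least lattice power (step dp) at which the
# covered area fraction reaches the target coverage, by direct counting
oracle_power_scan <- function(phi, area, targets, p_max_scan = 500, dp = 0.1) {
  af <- area / sum(area)
  for (p in seq(dp, p_max_scan, by = dp)) {
    if (sum(af[p * phi >= targets$target]) >= targets$coverage - 1e-12)
      return(p)
  }
  Inf
}

# direct-counting hotspot check
oracle_hotspot <- function(phi, area, targets, p) {
  sum(area[p * phi >= targets$hotspot_limit]) / sum(area) <=
    targets$hotspot_fraction + 1e-12
}

# Friedman chi-square-form statistic from a matrix of within-block ranks
oracle_friedman_stat <- function(ranks) {
  b <- nrow(ranks); k <- ncol(ranks)
  cs <- colSums(ranks)
  tie <- sum(apply(ranks, 1, function(x) { t <- table(x); sum(t^3 - t) }))
  12 * sum((cs - b * (k + 1) / 2)^2) / (b * k * (k + 1) - tie / (k - 1))
}

# cache for expensive shared fixtures (phantoms, MC runs), built once per
# test session
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

sphere_phantom_r2 <- function() {
  fixture("sphere_r2", function()
    generate_phantom(phantom_spec("sphere", radius = 2, seed = 1)))
}

sphere_phantom_small <- function() {
  fixture("sphere_r1", function()
    generate_phantom(phantom_spec("sphere", radius = 1, seed = 1,
                                  padding = 1.0)))
}
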