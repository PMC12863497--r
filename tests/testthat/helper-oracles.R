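# Independent oracles used across the suite. These deliberately use a
# different formulation than the package implementation.

# Brute-force MSI adjacency counts: per-voxel loop over all ordered neighbor
# offsets; ordered counts O(a,b) are then folded into the unordered-symmetric
# convention (off-diagonal N(i,j) = O(i,j); diagonal N(i,i) = O(i,i)/2).
brute_msi <- function(lab, k, connectivity = 6) {
  d <- dim(lab)
  offs <- if (connectivity == 6) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  O <- matrix(0, k + 1, k + 1)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lab[x, y, z]
    for (r in seq_len(nrow(offs))) {
      xx <- x + offs[r, 1]; yy <- y + offs[r, 2]; zz <- z + offs[r, 3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3]) next
      b <- lab[xx, yy, zz]
      if (a == 0 && b == 0) next
      O[a + 1, b + 1] <- O[a + 1, b + 1] + 1
    }
  }
  N <- O
  diag(N) <- diag(O) / 2
  dimnames(N) <- list(0:k, 0:k)
  N
}

# all-pairs concordance count AUC (ties 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# random small subregion label map (0 background + labels 1..k)
random_labelmap <- function(k = 3, max_dim = 12) {
  d <- sample(4:max_dim, 3, replace = TRUE)
  lab <- array(sample(0:k, prod(d), replace = TRUE,
                      prob = c(0.4, rep(0.6 / k, k))), dim = d)
  if (!any(lab > 0)) lab[1] <- 1L
  lab
}

# quick synthetic lesion for supervoxel tests
small_nodule <- function(grade = "low", diameter = 14, seed = 1) {
  generate_nodule(nodule_recipe(grade, diameter_mm = diameter, seed = seed))
}

unit_voi <- function(nod) {
  cr <- crop_voi(nod$volume, nod$mask, 2L)
  list(unit = window_normalize(cr$volume), mask = cr$mask, hu = cr$volume)
}
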