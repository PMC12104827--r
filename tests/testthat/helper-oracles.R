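# Independent oracles used across tests.  These are deliberately naive
# re-derivations (dense algebra, explicit loops) of quantities the
# package computes by other means.

# shared root-to-MRCA path length for every tip pair, by explicit
# node-depth walking over the edge matrix
vcv_path_oracle <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # process edges parents-first
  ord <- order(match(tree$edge[, 1], c(root, sort(unique(tree$edge[, 2])))))
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      d <- depth[p] + tree$edge.length[e]
      if (depth[ch] != d) { depth[ch] <- d; done <- FALSE }
    }
    if (done) break
  }
  mr <- ape::mrca(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    V[i, j] <- if (i == j) depth[i] else depth[mr[i, j]]
  }
  V
}

# textbook dense-matrix GLS estimate
gls_dense_oracle <- function(y, X, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
}

# build a censored_values-shaped data frame directly on the log scale
make_censored_df <- function(species, y, bound, metal = "Pb") {
  cens <- y < bound
  data.frame(specimen_id = seq_along(y),
             butterfly_species = species,
             metal = metal,
             y = ifelse(cens, NA_real_, y),
             censored = cens,
             bound = bound,
             stringsAsFactors = FALSE)
}

# minimal well-formed Ames record table
make_ames_df <- function(family, order, outcome,
                         strain = "TA98", solvent = "aqueous",
                         activation = 0L) {
  n <- length(outcome)
  data.frame(study_id = sprintf("s%03d", seq_len(n)),
             plant_species = paste0(family, "_sp"),
             plant_family = family,
             plant_order = order,
             tissue = "leaf",
             solvent_class = rep_len(solvent, n),
             strain = rep_len(strain, n),
             metabolic_activation = rep_len(activation, n),
             outcome = outcome,
             stringsAsFactors = FALSE)
}
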