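# small systems built in code for the unit tests

# bare bead cloud with no interactions defined
empty_topology <- function() {
  topo <- npcbarrier:::bare_topology(matrix(numeric(0), 0, 3))
  for (f in c("kind", "mobile", "chain")) topo[[f]] <- integer(0)
  for (f in c("hyd", "charge", "evr", "mass")) topo[[f]] <- numeric(0)
  topo
}

# a single rigid particle (cargo of diameter D) at `center`
free_particle <- function(center = c(0, 0, 0), D = 1, free_rotate = TRUE) {
  add_cargo(empty_topology(), make_inert_cargo(D), center = center,
            free_rotate = free_rotate)
}

# an n-bead FG-like chain with bonds/angles/dihedrals and random residues
random_chain_topology <- function(n, seed = 1, jitter = 0.02) {
  with_seed(seed, {
    pos <- matrix(0, n, 3)
    d <- c(1, 0, 0)
    for (i in seq_len(n)[-1]) {
      d <- d + rnorm(3, sd = 0.6)
      d <- d / sqrt(sum(d^2))
      pos[i, ] <- pos[i - 1, ] + 0.38 * d
    }
    pos <- pos + matrix(rnorm(3 * n, sd = jitter), n, 3)
    topo <- npcbarrier:::bare_topology(pos)
    topo$bonds <- cbind(seq_len(n - 1), 2:n)
    topo$bond_k <- rep(8000, n - 1)
    topo$bond_r0 <- rep(0.38, n - 1)
    if (n >= 3) topo$angles <- cbind(1:(n - 2), 2:(n - 1), 3:n)
    if (n >= 4) topo$dihedrals <- cbind(1:(n - 3), 2:(n - 2), 3:(n - 1), 4:n)
    topo$exclusions <- rbind(cbind(seq_len(n - 1), 2:n),
                             if (n >= 3) cbind(1:(n - 2), 3:n))
    topo$hyd <- runif(n)
    topo$charge <- sample(c(-1, 0, 0, 1), n, replace = TRUE)
    topo
  })
}

# central-difference force check; returns max |F_num - F| / max |F|
gradient_error <- function(topo, ff, terms = 15L, h = 1e-5) {
  res <- compute_energy(topo, ff, terms = terms)
  n <- nrow(topo$pos)
  num <- matrix(0, n, 3)
  for (i in seq_len(n)) for (k in 1:3) {
    tp <- topo; tp$pos[i, k] <- tp$pos[i, k] + h
    tm <- topo; tm$pos[i, k] <- tm$pos[i, k] - h
    num[i, k] <- -(compute_energy(tp, ff, terms = terms)$total -
                   compute_energy(tm, ff, terms = terms)$total) / (2 * h)
  }
  max(abs(num - res$forces)) / max(max(abs(res$forces)), 1e-8)
}

# tiny two-sequence set used by FASTA / grafting tests
demo_sequences <- c(nupA = "FSFGSTNQSAFSFG", nupB = "GSTNQFSFGAKDST")
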