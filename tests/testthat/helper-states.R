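# shared helpers for building random states and schemes

random_state <- function() {
  x <- runif(8)
  setNames(x / sum(x), haplotype_names())
}

random_scheme <- function() {
  recombination_scheme(r1 = runif(1, 0, 0.5), r2 = runif(1, 0, 0.5),
                       R = runif(1, 0, 0.5))
}

# independent two-locus oracle for plasticity-target LD decay: with a
# monomorphic modifier background the plasticity-target pair follows the
# classical recursion D' = (1 - r) D with unchanged marginals
two_locus_next <- function(fM, fd, D, r) {
  Dn <- (1 - r) * D
  c(Md = fM * fd + Dn, Ma = fM * (1 - fd) - Dn,
    md = (1 - fM) * fd - Dn, ma = (1 - fM) * (1 - fd) + Dn)
}
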