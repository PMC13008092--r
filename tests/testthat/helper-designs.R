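# Shared fixture builders. Everything is generated in code at test time.

two_block_meta <- function(p = 20) {
  data.frame(label = paste0("n", seq_len(p)),
             construct = rep(c("A", "B"), each = p / 2),
             measure = rep(c("objective", "subjective"), p / 2),
             stringsAsFactors = FALSE)
}

# pure two-block design with one planted bridge (third node of each block
# by default)
two_block_design <- function(p = 20, within_coupling = 1,
                             within_density = 0.3,
                             bridge = NULL,
                             negative_fraction = 0.1) {
  if (is.null(bridge))
    bridge <- list(paste0("n", c(3, p / 2 + 3)))
  planted_design(two_block_meta(p),
                 within_coupling = within_coupling,
                 between_coupling = 0.15,
                 bridge_coupling = max(1, within_coupling),
                 within_density = within_density,
                 between_density = 0,
                 bridge_pairs = bridge,
                 negative_fraction = negative_fraction,
                 threshold_mean = -1, threshold_sd = 0.25)
}

# small weighted network from an explicit matrix
net_from_matrix <- function(w, construct = NULL) {
  p <- nrow(w)
  meta <- data.frame(label = paste0("v", seq_len(p)),
                     construct = if (is.null(construct))
                       rep("A", p) else construct,
                     measure = "subjective", stringsAsFactors = FALSE)
  weighted_network(w, meta)
}

# random symmetric weight matrix: each pair carries a nonzero weight with
# probability `density`, uniform magnitude in [0.2, 1], sign negative with
# probability `neg`
random_weight_matrix <- function(p, density = 0.6, neg = 0) {
  w <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (runif(1) < density) {
        s <- if (runif(1) < neg) -1 else 1
        w[i, j] <- w[j, i] <- s * runif(1, 0.2, 1)
      }
    }
  }
  w
}
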