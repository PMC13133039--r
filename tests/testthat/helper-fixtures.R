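# compact constructors for hand-built gene tables and architectures

# genes from a vector of architecture signatures; coordinates are laid
# out left to right with fixed spacing
make_replicon <- function(signatures, strands = NULL, replicon_id = "rep1",
                          strain_id = "S1", rep_type = "chromosome",
                          lengths_aa = NULL, pseudo = NULL) {
  n <- length(signatures)
  strands <- strands %||% rep("+", n)
  lengths_aa <- lengths_aa %||% rep(300L, n)
  pseudo <- pseudo %||% rep(FALSE, n)
  width <- lengths_aa * 3L + 3L
  start <- cumsum(c(1L, (width + 100L)[-n]))
  genes <- data.frame(replicon_id = replicon_id, strain_id = strain_id,
                      rep_type = rep_type, index = seq_len(n) - 1L,
                      locus_tag = sprintf("%s_g%03d", replicon_id, seq_len(n)),
                      strand = strands, start = start,
                      end = start + width - 1L,
                      protein_id = sprintf("%s_p%03d", replicon_id, seq_len(n)),
                      length_aa = lengths_aa, pseudo = pseudo,
                      stringsAsFactors = FALSE)
  arch <- data.frame(protein_id = genes$protein_id, signature = signatures,
                     covered_aa = 100L, protein_length = lengths_aa,
                     stringsAsFactors = FALSE)
  list(genes = genes, arch = arch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a two-block distance matrix: tight within, far between
two_block_matrix <- function(n1 = 5, n2 = 5, within = 0.1, between = 0.9) {
  n <- n1 + n2
  d <- matrix(between, n, n)
  d[seq_len(n1), seq_len(n1)] <- within
  d[n1 + seq_len(n2), n1 + seq_len(n2)] <- within
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("x%02d", seq_len(n))
  d
}
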