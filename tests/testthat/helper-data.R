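# Shared builders for in-code fixtures.

test_design <- function() channel_design()

# One protein's peptide rows from explicit per-channel ratio vectors
# (reference column filled with 1s).
peptide_block <- function(accession, ch_114, ch_115, ch_116,
                          gene = accession, is_unique = TRUE) {
  k <- length(ch_114)
  data.frame(accession = accession, gene = gene,
             peptide_id = sprintf("%s_p%02d", accession, seq_len(k)),
             is_unique = rep_len(is_unique, k),
             ch_113 = rep(1, k), ch_114 = ch_114, ch_115 = ch_115,
             ch_116 = ch_116, stringsAsFactors = FALSE)
}

# Log-normal peptide ratios around a latent level.
lognorm_ratios <- function(n, level, sigma) level * exp(rnorm(n, 0, sigma))

# Table 4 fixture reshaped as a protein rollup table (printed channel
# values as protein-level values).
table4_as_proteins <- function() {
  t4 <- load_fixture("table4_candidates")
  data.frame(accession = t4$uniprot_id, gene = t4$gene,
             ch_113 = 1, ch_114 = t4$ch_114, ch_115 = t4$ch_115,
             ch_116 = t4$ch_116, cp_ratio = t4$cp_ratio,
             stringsAsFactors = FALSE)
}

table4_mapping <- function() {
  t4 <- load_fixture("table4_candidates")
  data.frame(accession = t4$uniprot_id, swissprot_id = t4$swissprot_id,
             gene = t4$gene, stringsAsFactors = FALSE)
}
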