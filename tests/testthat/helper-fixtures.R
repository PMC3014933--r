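# Shared fixtures: hand-built annotation rows and small simulation scenarios.

# construct an annotation row without going through a file
rm_row <- function(query_id, qb, qe, strand, name, class, cb, ce, id,
                   qleft = 1000L, cons_len = 310L, sw = 2000L, div = 10) {
  data.frame(sw_score = as.integer(sw), pct_div = div, pct_del = 1.0,
             pct_ins = 1.0, query_id = query_id,
             query_begin = as.integer(qb), query_end = as.integer(qe),
             query_left = as.integer(qleft), strand = strand,
             repeat_name = name, repeat_class = class,
             cons_begin = as.integer(cb), cons_end = as.integer(ce),
             cons_left = as.integer(cons_len - ce), element_id = as.integer(id),
             overlap_flag = FALSE, stringsAsFactors = FALSE)
}

# classic nested-insertion fixture: an AluSq (ID 6) inserted into an AluJb
# fragmented into two same-strand parts (ID 5), TSD overlap 10 nt
nested_fixture <- function() {
  rbind(
    rm_row("chr_test", 1001, 1150, "+", "AluJb", "SINE/Alu", 1, 150, 5),
    rm_row("chr_test", 1151, 1450, "+", "AluSq", "SINE/Alu", 1, 300, 6),
    rm_row("chr_test", 1451, 1610, "+", "AluJb", "SINE/Alu", 141, 300, 5)
  )
}

# three-level nest: A (deepest, ID 3) in B (ID 2) in C (ID 1); all plus strand
chain_fixture <- function() {
  rbind(
    rm_row("chr_chain",  501,  650, "+", "AluY",  "SINE/Alu", 1, 150, 1),   # C left
    rm_row("chr_chain",  651,  750, "+", "AluSx", "SINE/Alu", 1, 100, 2),   # B left
    rm_row("chr_chain",  751, 1050, "+", "AluJo", "SINE/Alu", 1, 300, 3),   # A
    rm_row("chr_chain", 1051, 1250, "+", "AluSx", "SINE/Alu", 91, 290, 2),  # B right
    rm_row("chr_chain", 1251, 1400, "+", "AluY",  "SINE/Alu", 141, 290, 1)  # C right
  )
}

# small, fast simulation: 3 subtypes, ~600 elements
small_sim_config <- function(seed = 7L, ...) {
  simulation_config(
    types = data.frame(
      name = c("AluJo", "AluSx", "AluY"), class = "SINE/Alu",
      copy_number = 200L, peak = c(0, 2, 4), sigma = 1,
      consensus_length = 300L, stringsAsFactors = FALSE),
    genome_background = 30000, n_loci = 120, seed = seed, ...)
}
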