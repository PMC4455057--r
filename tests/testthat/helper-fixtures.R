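# Small hand-built fixtures: a toy taxonomy and hit-list builders that
# let the orthology/screening/calling rules be tested without running the
# similarity search.

toy_taxa <- function() {
  data.frame(
    organism_id = c("ma", "mb", "mc", "fx", "fy", "fz",
                    "ar1", "ar2", "ar3", "ar4",
                    "c1", "c2", "p1", "p2", "f1", "f2"),
    name = "toy",
    domain = c(rep("Archaea", 10), rep("Bacteria", 6)),
    year = c(2001, 2002, 2003, 2004, 2005, 2006,
             2001, 2007, 2002, 2003, 2001, 2002, 2001, 2002, 2001, 2002),
    lineage = c(
      sprintf("domain:Archaea;family:MFam;genus:MGen;species:MGen_sp%d", 1:3),
      sprintf("domain:Archaea;family:MFam;genus:FGen%d;species:FGen%d_sp",
              1:3, 1:3),
      sprintf("domain:Archaea;phylum:APhy2;genus:OutGen;species:Out_sp%d",
              1:4),
      sprintf("domain:Bacteria;phylum:Firmicutes;class:Clostridia;genus:CGen%d;species:CGen%d_sp",
              1:2, 1:2),
      sprintf("domain:Bacteria;phylum:Proteobacteria;genus:PGen%d;species:PGen%d_sp",
              1:2, 1:2),
      sprintf("domain:Bacteria;phylum:Firmicutes;class:Bacilli;genus:BGen%d;species:BGen%d_sp",
              1:2, 1:2)),
    stringsAsFactors = FALSE)
}

toy_focal <- function(...) {
  focal_config(focal_species = c("ma", "mb", "mc"),
               focal_family = c("ma", "mb", "mc", "fx", "fy", "fz"), ...)
}

# A hit row with sane defaults; identity/coverage chosen to pass the
# screen thresholds unless overridden.
hit_row <- function(query, subject, score, identity = 60,
                    hsp_length = 150, coverage = 95) {
  data.frame(query_id = query, subject_id = subject, identity = identity,
             hsp_length = hsp_length, query_coverage = coverage,
             score = score, rank = NA_integer_, stringsAsFactors = FALSE)
}

# Assemble a ranked hit list from rows (score-desc, subject tie-break).
hit_list <- function(...) {
  h <- rbind(...)
  h <- h[order(-h$score, h$subject_id), ]
  h$rank <- seq_len(nrow(h))
  rownames(h) <- NULL
  h
}

# Map protein ids like "ma_3" to organism "ma" (toy convention).
toy_protein_orgs <- function(ids) {
  stats::setNames(sub("_[0-9]+$", "", ids), ids)
}
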