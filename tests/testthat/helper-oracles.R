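# Independent brute-force oracles and small random-fixture builders used
# across the suite. The oracles re-derive expected answers by exhaustive
# walking/counting, never through the package's graph machinery.

# kind by accession prefix, independent of any parsed object
oracle_kind <- function(accession) {
  prefix <- substr(accession, 3, 3)
  c(A = "submission", P = "study", X = "experiment",
    R = "run", S = "sample", Z = "analysis")[[prefix]]
}

# Transitive-closure resolution by naive fixed-point expansion over the
# allowed step relation (run->exp, exp->study, analysis->study,
# submission->owned, sample->exp reversed).
oracle_resolve <- function(objects, accession) {
  acc_set <- objects$accession
  steps <- list()
  for (i in seq_len(nrow(objects))) {
    from <- objects$accession[i]
    fk <- oracle_kind(from)
    refs <- objects$references[[i]]
    for (j in seq_len(nrow(refs))) {
      to <- refs$accession[j]
      if (!to %in% acc_set || to == from) next
      tk <- oracle_kind(to)
      ok <- (fk == "run" && tk == "experiment") ||
        (fk == "experiment" && tk == "study") ||
        (fk == "analysis" && tk == "study") ||
        (fk == "submission")
      if (ok) steps[[length(steps) + 1]] <- c(from, to)
      if (fk == "experiment" && tk == "sample") {
        steps[[length(steps) + 1]] <- c(to, from)
      }
    }
  }
  if (!accession %in% acc_set) return(character())
  reach <- accession
  repeat {
    nxt <- unique(c(reach, unlist(lapply(steps, function(s)
      if (s[1] %in% reach) s[2] else NULL))))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  sort(reach[vapply(reach, oracle_kind, "") == "study"])
}

# Random small metadata-object sets exercising one-to-many links, missing
# objects and dangling references.
random_objects <- function(n_studies = 4, p_dangling = 0.15) {
  objs <- list()
  exp_n <- 0
  run_n <- 0
  samp_n <- 0
  shared_sample <- NULL
  for (i in seq_len(n_studies)) {
    sp <- sprintf("SRP%06d", i)
    has_study <- runif(1) > 0.1
    if (has_study) {
      objs[[length(objs) + 1]] <- sra_object(
        "study", sp,
        study_type = sample(c("Whole Genome Sequencing",
                              "Transcriptome Analysis", NA), 1))
    }
    owned <- if (has_study) tibble::tibble(kind = "study", accession = sp)
             else NULL
    for (e in seq_len(sample(0:3, 1))) {
      exp_n <- exp_n + 1
      sx <- sprintf("SRX%06d", exp_n)
      refs <- tibble::tibble(kind = "study", accession = sp)
      # occasionally a second (possibly dangling) study link: one-to-many
      if (runif(1) < 0.2) {
        extra <- sprintf("SRP%06d", sample(n_studies + 0:2, 1))
        refs <- rbind(refs, tibble::tibble(kind = "study", accession = extra))
      }
      if (runif(1) < 0.7) {
        samp_n <- samp_n + 1
        ss <- sprintf("SRS%06d", samp_n)
        if (runif(1) < 0.3 && !is.null(shared_sample)) ss <- shared_sample
        shared_sample <- ss
        if (runif(1) > p_dangling) {
          objs[[length(objs) + 1]] <- sra_object("sample", ss,
                                                 taxon_id = 9606,
                                                 scientific_name = "Homo sapiens")
        }
        refs <- rbind(refs, tibble::tibble(kind = "sample", accession = ss))
      }
      objs[[length(objs) + 1]] <- sra_object("experiment", sx,
                                             references = refs)
      owned <- rbind(owned, tibble::tibble(kind = "experiment", accession = sx))
      for (r in seq_len(sample(0:2, 1))) {
        run_n <- run_n + 1
        sr <- sprintf("SRR%06d", run_n)
        objs[[length(objs) + 1]] <- sra_object(
          "run", sr,
          references = tibble::tibble(kind = "experiment", accession = sx))
        owned <- rbind(owned, tibble::tibble(kind = "run", accession = sr))
      }
    }
    objs[[length(objs) + 1]] <- sra_object(
      "submission", sprintf("SRA%06d", i),
      references = if (is.null(owned)) NULL else owned)
  }
  # drop duplicated accessions (shared samples emitted twice)
  out <- dplyr::bind_rows(objs)
  out[!duplicated(out$accession), ]
}

# three-level chain fixture used by several files
chain_objects <- function() {
  dplyr::bind_rows(
    sra_object("study", "SRP000010", title = "Chain study",
               study_type = "Whole Genome Sequencing"),
    sra_object("experiment", "SRX000050",
               instrument_model = "Illumina HiSeq 2000",
               references = tibble::tibble(kind = "study",
                                           accession = "SRP000010")),
    sra_object("run", "SRR000101",
               references = tibble::tibble(kind = "experiment",
                                           accession = "SRX000050"))
  )
}
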