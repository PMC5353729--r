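# Synthetic CHS family generator.
#
# Emulates the statistical structure the analysis assumes: a root CON1
# sequence carrying the three motifs is evolved down a fixed two-level tree
# (3 divisions -> 7 classes plus the basal 23b lineage) at between-class
# divergence, then within-class copies at within-class divergence, with
# motif columns frozen; full proteins are assembled as flank +
# class-appropriate domain segments + CON1 + flank with a matching
# domain-hit table; decoys lack motifs or characteristic domains; noisy
# Type-B1 proteins carry a CON1 with no class signal; gene models plant
# head-to-head ChsV/ChsVII pairs at a configurable rate.
#
# Substitutions follow a Jukes-Cantor-style protein model: per site a
# Poisson(t) number of substitution events, each drawing uniformly from the
# 19 alternative residues, so the expected observed p-distance for path
# length t is (19/20) * (1 - exp(-20 t / 19)).

#' Simulation configuration
#'
#' Defaults reflect the survey's reported conditions: CON1 length 141 (the
#' reported mean), a filamentous-fungus repertoire of one member per class,
#' an early-diverging repertoire expanded with unclassifiable Type-B1
#' copies, head-to-head ChsV/ChsVII in 95% of two-gene species and an
#' intervening hypothetical gene in 17/95 of those.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_species Number of species.
#' @param prop_early Fraction of species tagged early-diverging.
#' @param repertoire,early_repertoire Named counts per class label (plus
#'   `noisy_B1`) for dikarya-like and early-diverging-like species.
#' @param n_decoys_motif_free,n_decoys_domain_free Planted decoys per
#'   species.
#' @param within_class_divergence,between_class_divergence Expected
#'   substitutions per mutable site along the path between two members of
#'   the same class / the class-tree scale.
#' @param con1_length CON1 region length (aa).
#' @param flank_length,domain_lengths,cs2_padding Protein assembly segment
#'   sizes (aa).
#' @param head_to_head_fraction Probability that a species with both ChsV
#'   and ChsVII gets a head-to-head pair.
#' @param intervening_gene_probability Probability that a planted
#'   head-to-head pair has one hypothetical gene between the two.
#' @param n_ref_per_class Reference CON1 sequences per class label.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_species = 12,
                       prop_early = 0.25,
                       repertoire = c(I = 1, II = 1, III = 1, IV = 1,
                                      V = 1, VI = 1, VII = 1, "23b" = 0,
                                      noisy_B1 = 0),
                       early_repertoire = c(I = 1, II = 1, III = 3, IV = 3,
                                            V = 1, VI = 0, VII = 1,
                                            "23b" = 0, noisy_B1 = 8),
                       n_decoys_motif_free = 1,
                       n_decoys_domain_free = 1,
                       within_class_divergence = 0.05,
                       between_class_divergence = 0.5,
                       con1_length = 141,
                       flank_length = 30,
                       domain_lengths = c(PF08407 = 120, PF01644 = 200,
                                          PF00173 = 80, PF00063 = 250,
                                          PF08766 = 60),
                       cs2_padding = 20,
                       head_to_head_fraction = 0.95,
                       intervening_gene_probability = 17 / 95,
                       n_ref_per_class = 3) {
  cfg <- as.list(environment())
  valid <- c(CLASS_LABELS, "noisy_B1")
  for (f in c("repertoire", "early_repertoire")) {
    if (!all(names(cfg[[f]]) %in% valid)) {
      stop("unknown class labels in ", f, ": ",
           paste(setdiff(names(cfg[[f]]), valid), collapse = ", "))
    }
    if (any(cfg[[f]] < 0)) stop("negative counts in ", f)
  }
  if (within_class_divergence < 0 || between_class_divergence < 0)
    stop("divergences must be non-negative")
  if (within_class_divergence > between_class_divergence)
    warning("within-class divergence exceeds between-class divergence; ",
            "classes will not be identifiable")
  if (con1_length < 25) stop("con1_length too short for three motifs")
  structure(cfg, class = "sim_config")
}

#' Expected p-distance for a path of t substitutions per site
#'
#' Closed form under the uniform 20-residue substitution model used by the
#' simulator.
#' @param t Expected substitutions per (mutable) site.
#' @return Expected proportion of differing sites.
#' @export
expected_p_distance <- function(t) (19 / 20) * (1 - exp(-20 * t / 19))

rand_aa <- function(n) sample(AA_ALPHABET, n, replace = TRUE)

# root CON1 as a character vector plus frozen motif site indices
make_root_con1 <- function(L) {
  mid <- floor((L - 5) / 2) + 1L
  pos_start <- 1:5
  pos_mid <- mid:(mid + 4L)
  pos_end <- (L - 4L):L
  motif_idx <- c(pos_start, pos_mid, pos_end)
  repeat {
    s <- rand_aa(L)
    s[pos_start] <- c("Q", sample(AA_ALPHABET, 1), sample(AA_ALPHABET, 1),
                      "E", "Y")
    s[pos_mid] <- c("E", "D", "R", sample(AA_ALPHABET, 1), "L")
    s[pos_end] <- c("Q", sample(AA_ALPHABET, 1), "R", "R", "W")
    if (con1_is_clean(paste(s, collapse = ""))) break
  }
  list(chars = s, free_idx = setdiff(seq_len(L), motif_idx))
}

# exactly one occurrence of each primary motif
con1_is_clean <- function(seq) {
  hits <- scan_motifs(seq)
  nrow(hits) == 3 && setequal(hits$motif_name, c("QxxEY", "EDRxL", "QxRRW"))
}

mutate_chars <- function(chars, t, free_idx) {
  nsub <- stats::rpois(length(free_idx), t)
  for (k in which(nsub > 0)) {
    site <- free_idx[k]
    for (m in seq_len(nsub[k])) {
      chars[site] <- sample(setdiff(AA_ALPHABET, chars[site]), 1)
    }
  }
  chars
}

evolve_clean <- function(chars, t, free_idx, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    out <- mutate_chars(chars, t, free_idx)
    if (con1_is_clean(paste(out, collapse = ""))) return(out)
  }
  stop("could not evolve a motif-clean CON1 sequence")
}

# class consensuses along the fixed two-level tree
make_class_consensuses <- function(root, b) {
  ev <- function(x, t) evolve_clean(x, t, root$free_idx)
  d1 <- ev(root$chars, b / 2)
  d2 <- ev(root$chars, b / 2)
  d3 <- ev(root$chars, b / 2)
  anc_b <- ev(d1, b / 4)       # basal split: 23b vs (II, III)
  anc23 <- ev(anc_b, b / 8)
  ancvv <- ev(d2, b / 4)       # V/VII tandem ancestor
  list(I = ev(d1, b / 2),
       "23b" = ev(anc_b, b / 4),
       II = ev(anc23, b / 8),
       III = ev(anc23, b / 8),
       IV = ev(d2, b / 2),
       V = ev(ancvv, b / 4),
       VII = ev(ancvv, b / 4),
       VI = ev(d3, b / 2),
       root = root$chars)
}

# assemble a full protein around a CON1 character vector; returns sequence,
# planted CON1 coordinates (0-based half-open) and its domain-hit rows
assemble_protein <- function(pid, con1_chars, kind, cfg) {
  fl <- cfg$flank_length
  dl <- cfg$domain_lengths
  pad <- cfg$cs2_padding
  Lc <- length(con1_chars)
  seg <- function(n) rand_aa(n)
  hit <- function(acc, start, end, score) {
    data.frame(protein_id = pid, accession = acc, start = start, end = end,
               score = score, evalue = 1e-25, stringsAsFactors = FALSE)
  }
  parts <- list()
  hits <- list()
  pos <- 0L
  add <- function(chars) {
    parts[[length(parts) + 1L]] <<- chars
    old <- pos
    pos <<- pos + length(chars)
    c(old, pos)  # 0-based half-open extent of the segment
  }
  add(seg(fl))
  con1_span <- NULL
  if (kind %in% c("I", "II", "III", "23b")) {
    e1 <- add(seg(dl[["PF08407"]]))
    e2 <- add(seg(dl[["PF01644"]]))
    con1_span <- add(con1_chars)
    hits <- list(hit("PF08407", e1[1], e1[2], 60),
                 hit("PF01644", e2[1], e2[2], 150),
                 # truncated CS2 remnant inside the CON1 region
                 hit("PF03142", con1_span[1] + 5L, con1_span[2] - 5L, 40))
  } else if (kind == "IV") {
    e1 <- add(seg(dl[["PF00173"]]))
    p1 <- add(seg(pad)); con1_span <- add(con1_chars); p2 <- add(seg(pad))
    hits <- list(hit("PF00173", e1[1], e1[2], 70),
                 hit("PF03142", p1[1], p2[2], 200))
  } else if (kind %in% c("V", "VII")) {
    e0 <- add(seg(dl[["PF00063"]]))
    e1 <- add(seg(dl[["PF00173"]]))
    p1 <- add(seg(pad)); con1_span <- add(con1_chars); p2 <- add(seg(pad))
    e3 <- add(seg(dl[["PF08766"]]))
    hits <- list(hit("PF00063", e0[1], e0[2], 180),
                 hit("PF00173", e1[1], e1[2], 70),
                 hit("PF03142", p1[1], p2[2], 200),
                 hit("PF08766", e3[1], e3[2], 55))
  } else if (kind %in% c("VI", "noisy_B1")) {
    p1 <- add(seg(pad)); con1_span <- add(con1_chars); p2 <- add(seg(pad))
    hits <- list(hit("PF03142", p1[1], p2[2], 200))
  } else if (kind == "decoy_domain_free") {
    a1 <- add(seg(20))
    con1_span <- add(con1_chars)
    hits <- list(hit("PF07690", a1[1], a1[2], 30))  # auxiliary only
  } else stop("unknown protein kind: ", kind)
  add(seg(fl))
  list(sequence = paste(unlist(parts), collapse = ""),
       con1_start = con1_span[1], con1_end = con1_span[2],
       hits = do.call(rbind, hits))
}

planted_type <- function(kind) {
  switch(kind,
         I = , II = , III = , "23b" = "A2",
         IV = "B2", V = , VII = "B4",
         VI = , noisy_B1 = "B1",
         NA_character_)
}

# build a protein whose whole-sequence CON1 extraction matches the plant
build_protein_checked <- function(pid, con1_chars, kind, cfg,
                                  max_tries = 50) {
  for (i in seq_len(max_tries)) {
    p <- assemble_protein(pid, con1_chars, kind, cfg)
    region <- extract_con1(p$sequence)
    if (!is.null(region) && region$start == p$con1_start &&
        region$end == p$con1_end) {
      return(p)
    }
  }
  stop("could not assemble a protein with unambiguous CON1 for ", pid)
}

make_motif_free_decoy <- function(pid, cfg, max_tries = 50) {
  n <- 2 * cfg$flank_length + 200L
  for (i in seq_len(max_tries)) {
    s <- paste(rand_aa(n), collapse = "")
    if (is.null(extract_con1(s))) {
      hits <- data.frame(protein_id = pid, accession = "PF03142",
                         start = 30L, end = 230L, score = 200,
                         evalue = 1e-25, stringsAsFactors = FALSE)
      return(list(sequence = s, con1_start = NA_integer_,
                  con1_end = NA_integer_, hits = hits))
    }
  }
  stop("could not generate a motif-free decoy")
}

#' Simulate a class-structured CHS family dataset
#'
#' @param config A [sim_config()].
#' @return A list of class `chs_simulation`: `proteins` (FASTA-ready record
#'   table), `domain_hits`, `gene_models` (with a `species_id` column),
#'   `taxonomy`, `reference` (a `con1_reference`), and `truth` (planted
#'   classes, types, CON1 coordinates and synteny arrangements). Byte-level
#'   deterministic for a fixed config.
#' @export
simulate_family <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    root <- make_root_con1(cfg$con1_length)
    cons <- make_class_consensuses(root, cfg$between_class_divergence)

    # labeled reference set
    ref_rows <- list()
    for (cls in CLASS_LABELS) {
      for (r in seq_len(cfg$n_ref_per_class)) {
        id <- sprintf("REF_%s_%d", cls, r)
        s <- evolve_clean(cons[[cls]], cfg$within_class_divergence / 2,
                          root$free_idx)
        ref_rows[[id]] <- list(id = id, cls = cls,
                               seq = paste(s, collapse = ""))
      }
    }
    ref_aln <- seq_to_matrix(setNames(
      vapply(ref_rows, function(r) r$seq, ""),
      vapply(ref_rows, function(r) r$id, "")))
    reference <- con1_reference(ref_aln, setNames(
      vapply(ref_rows, function(r) r$cls, ""),
      vapply(ref_rows, function(r) r$id, "")))

    n_early <- round(cfg$prop_early * cfg$n_species)
    proteins <- list(); hits <- list(); truth_p <- list()
    taxonomy <- list(); genes <- list(); truth_s <- list()

    for (si in seq_len(cfg$n_species)) {
      sid <- sprintf("SP%03d", si)
      early <- si <= n_early
      taxonomy[[si]] <- data.frame(
        species_id = sid,
        phylum = if (early) "Zygomycota" else "Ascomycota",
        subphylum = if (early) "Mucoromycotina" else "Pezizomycotina",
        class = if (early) "Mucoromycetes" else "Sordariomycetes",
        early_diverging = early, stringsAsFactors = FALSE)
      rep_counts <- if (early) cfg$early_repertoire else cfg$repertoire
      k <- 0L
      sp_prot <- list()
      new_pid <- function() {
        k <<- k + 1L
        sprintf("%sp%02d", sid, k)
      }
      for (kind in names(rep_counts)) {
        for (cc in seq_len(rep_counts[[kind]])) {
          pid <- new_pid()
          src <- if (kind == "noisy_B1") {
            # no class signal: drawn at between-class divergence off the root
            evolve_clean(root$chars, cfg$between_class_divergence,
                         root$free_idx)
          } else {
            evolve_clean(cons[[kind]], cfg$within_class_divergence / 2,
                         root$free_idx)
          }
          p <- build_protein_checked(pid, src, kind, cfg)
          sp_prot[[pid]] <- list(kind = kind, p = p)
        }
      }
      for (d in seq_len(cfg$n_decoys_motif_free)) {
        pid <- new_pid()
        sp_prot[[pid]] <- list(kind = "decoy_motif_free",
                               p = make_motif_free_decoy(pid, cfg))
      }
      for (d in seq_len(cfg$n_decoys_domain_free)) {
        pid <- new_pid()
        src <- evolve_clean(root$chars, cfg$between_class_divergence,
                            root$free_idx)
        sp_prot[[pid]] <- list(kind = "decoy_domain_free",
                               p = build_protein_checked(
                                 pid, src, "decoy_domain_free", cfg))
      }
      for (pid in names(sp_prot)) {
        e <- sp_prot[[pid]]
        proteins[[pid]] <- data.frame(protein_id = pid, species_id = sid,
                                      sequence = e$p$sequence,
                                      stringsAsFactors = FALSE)
        hits[[pid]] <- e$p$hits
        truth_p[[pid]] <- data.frame(
          protein_id = pid, species_id = sid, class = e$kind,
          type_label = planted_type(e$kind),
          con1_start = e$p$con1_start, con1_end = e$p$con1_end,
          stringsAsFactors = FALSE)
      }
      sp_genes <- plant_genes(sid, sp_prot, cfg)
      genes[[si]] <- sp_genes$models
      truth_s[[si]] <- sp_genes$truth
    }

    structure(list(
      proteins = do.call(rbind, c(unname(proteins), list(make.row.names = FALSE))),
      domain_hits = do.call(rbind, c(unname(hits), list(make.row.names = FALSE))),
      gene_models = do.call(rbind, c(unname(genes), list(make.row.names = FALSE))),
      taxonomy = do.call(rbind, c(taxonomy, list(make.row.names = FALSE))),
      reference = reference,
      truth = list(
        proteins = do.call(rbind, c(unname(truth_p), list(make.row.names = FALSE))),
        synteny = do.call(rbind, c(truth_s, list(make.row.names = FALSE)))),
      config = cfg), class = "chs_simulation")
  })
}

# one contig per species; genes laid left to right; the first V/VII pair is
# planted head-to-head with the configured probability
plant_genes <- function(sid, sp_prot, cfg) {
  contig <- paste0(sid, "_chr1")
  kinds <- vapply(sp_prot, function(e) e$kind, "")
  pids <- names(sp_prot)
  v_id <- pids[kinds == "V"][1]
  vii_id <- pids[kinds == "VII"][1]
  plant_hh <- !is.na(v_id) && !is.na(vii_id) &&
    stats::runif(1) < cfg$head_to_head_fraction
  with_intervening <- plant_hh &&
    stats::runif(1) < cfg$intervening_gene_probability
  v_left <- stats::runif(1) < 0.5

  exon_len <- 300L; intron_len <- 100L; gap <- 2000L
  rows <- list()
  cursor <- 1000L
  emit_gene <- function(gene_id, protein_id, strand, exon_count,
                        adjacent = FALSE) {
    glen <- exon_count * exon_len + (exon_count - 1L) * intron_len
    start <- cursor
    end <- start + glen - 1L
    cursor <<- end + (if (adjacent) 500L else gap)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene_id, protein_id = protein_id, contig = contig,
      start = start, end = end, strand = strand, exon_count = exon_count,
      species_id = sid, stringsAsFactors = FALSE)
  }
  exon_n <- function(kind) {
    if (kind %in% c("V", "VII")) sample(2:5, 1) else sample(1:4, 1)
  }
  pair <- character(0)
  if (plant_hh) pair <- c(v_id, vii_id)
  for (pid in pids) {
    if (pid %in% pair) next
    emit_gene(paste0("g_", pid), pid, "+", exon_n(kinds[pid == pids][1]))
  }
  if (!is.na(v_id) && !is.na(vii_id)) {
    if (plant_hh) {
      left <- if (v_left) v_id else vii_id
      right <- if (v_left) vii_id else v_id
      emit_gene(paste0("g_", left), left, "-",
                exon_n(kinds[pids == left][1]), adjacent = TRUE)
      if (with_intervening) {
        emit_gene(paste0(sid, "_hyp1"), NA_character_, "+", 1L,
                  adjacent = TRUE)
      }
      emit_gene(paste0("g_", right), right, "+",
                exon_n(kinds[pids == right][1]))
      truth_arr <- "head_to_head"
    } else {
      truth_arr <- "separate"
    }
  } else {
    truth_arr <- "absent"
  }
  list(models = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = data.frame(
         species_id = sid, planted = truth_arr,
         intervening = if (truth_arr == "head_to_head")
           as.integer(with_intervening) else NA_integer_,
         gene_v = if (is.na(v_id)) NA_character_ else paste0("g_", v_id),
         gene_vii = if (is.na(vii_id)) NA_character_ else paste0("g_", vii_id),
         stringsAsFactors = FALSE))
}

#' Write a simulated dataset to standard formats
#'
#' Writes `proteins.fasta`, `domain_hits.tsv`, `genes.gff3`,
#' `taxonomy.tsv`, `reference_con1.fasta` and `truth.json` into `out_dir`;
#' re-parsing these files reproduces the in-memory dataset.
#'
#' @param dataset A `chs_simulation` from [simulate_family()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(fasta = file.path(out_dir, "proteins.fasta"),
             hits = file.path(out_dir, "domain_hits.tsv"),
             gff = file.path(out_dir, "genes.gff3"),
             taxonomy = file.path(out_dir, "taxonomy.tsv"),
             reference = file.path(out_dir, "reference_con1.fasta"),
             truth = file.path(out_dir, "truth.json"))
  write_sequences(dataset$proteins, paths[["fasta"]])
  write_domain_hits(dataset$domain_hits, paths[["hits"]])
  write_gff3(dataset$gene_models, paths[["gff"]])
  write.table(dataset$taxonomy, paths[["taxonomy"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_con1_reference(dataset$reference, paths[["reference"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}

# exon layout mirrors plant_genes(): fixed 300-aa exons, 100-bp introns
write_gff3 <- function(models, path) {
  exon_len <- 300L; intron_len <- 100L
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    pid_attr <- if (is.na(g$protein_id)) "" else
      paste0(";protein_id=", g$protein_id)
    lines <- c(lines, sprintf(
      "%s\tchsfam_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
      g$contig, g$start, g$end, g$strand, g$gene_id, pid_attr))
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines, sprintf(
      "%s\tchsfam_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s%s",
      g$contig, g$start, g$end, g$strand, tid, g$gene_id, pid_attr))
    for (e in seq_len(g$exon_count)) {
      es <- g$start + (e - 1L) * (exon_len + intron_len)
      ee <- es + exon_len - 1L
      lines <- c(lines, sprintf(
        "%s\tchsfam_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        g$contig, es, ee, g$strand, tid, e, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
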