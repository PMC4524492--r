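# Seeded plastome evolution simulator.
#
# A genome is carried as an architecture: gene contents of the three
# single-copy-facing blocks (LSC, IR copy A, SSC) with signs, plus planted
# repeat specifications. The realized genome is LSC | IRA | SSC | IRB with
# IRB the exact reverse complement of IRA, so quadripartite invariants hold
# by construction. Evolution along a rooted tree applies Poisson numbers of
# events per branch: segmental inversions within a region, IR boundary
# shifts (one gene across a junction, duplicated/deduplicated in both
# copies), irreversible IR loss, and insertion of small direct/palindromic
# repeats. Every event is logged with explicit parameters so a truth log can
# be replayed to bit-identical tips.

#' Simulation configuration
#'
#' Defaults emulate a mid-sized AT-rich plastome with a quadripartite
#' architecture: 91 standard genes, a ~10-gene IR carrying the rDNA operon
#' transcribed toward the SSC, a ~120 kb length target at 65% A+T, and
#' modest per-branch event rates.
#'
#' @param n_genes Total distinct genes (>= 10).
#' @param ir_gene_count Genes in each IR copy, including the 5 rDNA operon
#'   genes (>= 5).
#' @param ssc_gene_count Genes in the SSC.
#' @param genome_length_target Approximate realized length in bp.
#' @param at_percent Target A+T percent.
#' @param rates Named per-branch Poisson event rates: `inversion`,
#'   `ir_expand`, `ir_contract`, `ir_loss`, `repeat_insert`.
#' @param repeat_len_range Min/max planted repeat length (bp).
#' @param use_core_symbols Use the packaged 91 standard symbols when
#'   `n_genes == 91`, otherwise synthetic symbols plus the operon genes.
#' @param fragment Optional list(symbol=, parts=) planting a fragmented gene.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 91L, ir_gene_count = 10L, ssc_gene_count = 4L,
                       genome_length_target = 120000L, at_percent = 65,
                       rates = c(inversion = 1, ir_expand = 0.2,
                                 ir_contract = 0.2, ir_loss = 0.05,
                                 repeat_insert = 0.5),
                       repeat_len_range = c(30L, 120L),
                       use_core_symbols = TRUE, fragment = NULL, seed) {
  if (missing(seed)) abort("sim_config requires an explicit seed")
  stopifnot(n_genes >= 10L, ir_gene_count >= 5L,
            ssc_gene_count >= 1L, all(rates >= 0),
            n_genes > ir_gene_count + ssc_gene_count)
  structure(list(n_genes = as.integer(n_genes),
                 ir_gene_count = as.integer(ir_gene_count),
                 ssc_gene_count = as.integer(ssc_gene_count),
                 genome_length_target = as.integer(genome_length_target),
                 at_percent = at_percent, rates = rates,
                 repeat_len_range = as.integer(repeat_len_range),
                 use_core_symbols = isTRUE(use_core_symbols),
                 fragment = fragment, seed = as.integer(seed)),
            class = "sim_config")
}

operon_symbols <- function() c("rrs", "trnI(gau)", "trnA(ugc)", "rrl", "rrf")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build the ancestral quadripartite architecture
#'
#' The ancestor carries the rDNA operon colinear inside the IR, at the
#' SSC-proximal end of IRA on the forward strand, i.e. transcribed toward
#' the SSC as in ancestral-pattern plastomes.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_arch` (gene blocks, gene lengths and
#'   sequences, planted repeats, `ir_present`).
#' @export
make_ancestor <- function(cfg) {
  with_seed(cfg$seed, {
    op <- operon_symbols()
    syms <- if (cfg$use_core_symbols && cfg$n_genes == 91L) {
      core91_cached()
    } else {
      c(op, sprintf("g%03d", seq_len(cfg$n_genes - length(op))))
    }
    stopifnot(length(syms) == cfg$n_genes, all(op %in% syms))
    rest <- setdiff(syms, op)
    # under the ancestral pattern the SSC holds the genes downstream of the
    # rDNA operon; with the standard symbol set those are the curated
    # SSC-side genes, so zero-event genomes classify with no deviations
    if (cfg$use_core_symbols && cfg$n_genes == 91L) {
      ssc_pool <- intersect(ancestral_sides()$symbol[
        ancestral_sides()$side == "ssc_side"], rest)
    } else {
      ssc_pool <- rest
    }
    ssc_g <- ssc_pool[seq_len(min(cfg$ssc_gene_count, length(ssc_pool)))]
    rest <- setdiff(rest, ssc_g)
    n_ir_extra <- cfg$ir_gene_count - length(op)
    ir_extra <- rest[seq_len(n_ir_extra)]
    lsc_g <- setdiff(rest, ir_extra)
    # mildly sided strand pattern in the single-copy regions
    blocky_signs <- function(n) {
      s <- integer(0)
      cur <- sample(c(1L, -1L), 1)
      while (length(s) < n) {
        run <- sample(2:6, 1)
        s <- c(s, rep(cur, run)); cur <- -cur
      }
      s[seq_len(n)]
    }
    arch <- list(
      lsc = tibble(symbol = lsc_g, sign = blocky_signs(length(lsc_g))),
      ir = tibble(symbol = c(ir_extra, op),
                  sign = rep(1L, cfg$ir_gene_count)),
      ssc = tibble(symbol = ssc_g, sign = blocky_signs(length(ssc_g))),
      ir_present = TRUE,
      repeats = tibble(region = character(), kind = character(),
                       seq = character(), slot1 = integer(), slot2 = integer()),
      gene_len = gene_lengths(syms),
      at_percent = cfg$at_percent)
    arch$gene_seq <- gene_sequences(arch$gene_len, cfg$at_percent)
    class(arch) <- "sim_arch"
    arch
  })
}

gene_lengths <- function(syms) {
  len <- integer(length(syms))
  names(len) <- syms
  for (s in syms) {
    len[s] <- if (s == "rrs") 1398L else if (s == "rrl") 2799L
      else if (s == "rrf") 120L else if (startsWith(s, "trn")) 72L
      else 3L * sample(150:450, 1)
  }
  len
}

gene_sequences <- function(gene_len, at_percent) {
  out <- lapply(gene_len, function(n) random_dna(n, at_percent))
  out
}

## ---------------------------------------------------------------------------
## Events

apply_event <- function(arch, type, params) {
  switch(type,
    inversion = {
      reg <- params$region
      blk <- arch[[reg]]
      i <- params$from; j <- params$to
      seg <- blk[i:j, , drop = FALSE]
      seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      seg$sign <- -seg$sign
      arch[[reg]] <- bind_rows(
        if (i > 1L) blk[1:(i - 1L), ] else NULL, seg,
        if (j < nrow(blk)) blk[(j + 1L):nrow(blk), ] else NULL)
      arch
    },
    ir_expand = {
      if (!arch$ir_present) return(arch)
      if (params$side == "lsc" && nrow(arch$lsc) > 2L) {
        g <- arch$lsc[nrow(arch$lsc), , drop = FALSE]
        arch$lsc <- arch$lsc[-nrow(arch$lsc), , drop = FALSE]
        arch$ir <- bind_rows(g, arch$ir)
      } else if (params$side == "ssc" && nrow(arch$ssc) > 2L) {
        g <- arch$ssc[1L, , drop = FALSE]
        arch$ssc <- arch$ssc[-1L, , drop = FALSE]
        arch$ir <- bind_rows(arch$ir, g)
      }
      arch
    },
    ir_contract = {
      if (!arch$ir_present || nrow(arch$ir) <= 5L) return(arch)
      if (params$side == "lsc") {
        g <- arch$ir[1L, , drop = FALSE]
        arch$ir <- arch$ir[-1L, , drop = FALSE]
        arch$lsc <- bind_rows(arch$lsc, g)
      } else {
        g <- arch$ir[nrow(arch$ir), , drop = FALSE]
        arch$ir <- arch$ir[-nrow(arch$ir), , drop = FALSE]
        arch$ssc <- bind_rows(g, arch$ssc)
      }
      arch
    },
    ir_loss = {
      arch$ir_present <- FALSE
      arch
    },
    repeat_insert = {
      arch$repeats <- bind_rows(arch$repeats, tibble(
        region = params$region, kind = params$kind, seq = params$seq,
        slot1 = params$slot1, slot2 = params$slot2))
      arch
    },
    abort(paste0("unknown event type: ", type)))
}

sample_event <- function(arch, type, cfg) {
  switch(type,
    inversion = {
      sizes <- c(lsc = nrow(arch$lsc),
                 ir = if (arch$ir_present) nrow(arch$ir) else 0L,
                 ssc = nrow(arch$ssc))
      ok <- names(sizes)[sizes >= 2L]
      reg <- if (length(ok) == 1L) ok else sample(ok, 1, prob = sizes[ok])
      n <- sizes[[reg]]
      ij <- sort(sample(n, 2L))
      list(region = reg, from = ij[1], to = ij[2])
    },
    ir_expand = list(side = sample(c("lsc", "ssc"), 1)),
    ir_contract = list(side = sample(c("lsc", "ssc"), 1)),
    ir_loss = list(),
    repeat_insert = {
      len <- sample(cfg$repeat_len_range[1]:cfg$repeat_len_range[2], 1)
      reg <- sample(c("lsc", "ssc"), 1, prob = c(3, 1))
      n_slots <- nrow(arch[[reg]]) + 1L
      list(region = reg, kind = sample(c("forward", "palindromic"), 1),
           seq = random_dna(len, 50), slot1 = sample(n_slots, 1),
           slot2 = sample(n_slots, 1))
    },
    abort(paste0("unknown event type: ", type)))
}

#' Evolve an ancestral architecture along a rooted tree
#'
#' Each branch receives Poisson numbers of events at the configured rates
#' (an IR loss is irreversible; IR events are skipped on IR-less lineages).
#' Tips are realized as [plastome] records; the returned truth log contains
#' the ancestor, the tree, every event with explicit parameters, and the
#' per-tip architecture, IR annotation and signed gene order.
#'
#' @param ancestor From [make_ancestor()].
#' @param tree Rooted `ape::phylo`.
#' @param cfg The [sim_config()] used for the ancestor.
#' @return List of class `truth_log`: `tips` (named list of `plastome`),
#'   `events` (tibble: branch, order, type, params JSON), `tip_arch`,
#'   `tip_ir`, `tip_order`, `tree`, `cfg`, `ancestor`.
#' @export
evolve_plastomes <- function(ancestor, tree, cfg) {
  stopifnot(inherits(ancestor, "sim_arch"), inherits(tree, "phylo"))
  with_seed(cfg$seed + 1L, {
    nt <- ape::Ntip(tree)
    nn <- nt + tree$Nnode
    arch_at <- vector("list", nn)
    root <- nt + 1L
    arch_at[[root]] <- ancestor
    events <- list()
    for (e in rev(ape::postorder(tree))) {  # parent-first
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      arch <- arch_at[[p]]
      branch <- node_label(tree, ch)
      types <- names(cfg$rates)
      n_ev <- rpois(length(types), cfg$rates)
      todo <- rep(types, n_ev)
      if (length(todo) > 1L) todo <- sample(todo)
      k <- 0L
      for (type in todo) {
        if (type %in% c("ir_expand", "ir_contract", "ir_loss") && !arch$ir_present) next
        if (type == "ir_loss" && !arch$ir_present) next
        params <- sample_event(arch, type, cfg)
        arch <- apply_event(arch, type, params)
        k <- k + 1L
        events[[length(events) + 1L]] <- tibble(
          branch = branch, node = ch, order = k, type = type,
          params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)))
      }
      arch_at[[ch]] <- arch
    }
    events <- if (length(events)) bind_rows(events) else
      tibble(branch = character(), node = integer(), order = integer(),
             type = character(), params = character())
    tips <- list(); tip_ir <- list(); tip_order <- list(); tip_arch <- list()
    for (i in seq_len(nt)) {
      tx <- tree$tip.label[i]
      real <- realize_tip(arch_at[[i]], cfg, tip_seed(cfg$seed, i), taxon = tx)
      tips[[tx]] <- real$genome
      tip_ir[[tx]] <- real$ir
      tip_order[[tx]] <- real$order
      tip_arch[[tx]] <- arch_at[[i]]
    }
    structure(list(tips = tips, events = events, tip_arch = tip_arch,
                   tip_ir = tip_ir, tip_order = tip_order, tree = tree,
                   cfg = cfg, ancestor = ancestor),
              class = "truth_log")
  })
}

tip_seed <- function(seed, i) (seed * 1009L + i * 9176L) %% 2147483647L

#' Replay a truth log
#'
#' Re-applies the recorded events from the stored ancestor and regenerates
#' every tip; the result is bit-identical to the original run.
#'
#' @param truth A `truth_log` from [evolve_plastomes()].
#' @return Named list of `plastome` tips.
#' @export
replay_truth_log <- function(truth) {
  tree <- truth$tree
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  arch_at <- vector("list", nn)
  arch_at[[nt + 1L]] <- truth$ancestor
  for (e in rev(ape::postorder(tree))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    arch <- arch_at[[p]]
    ev <- truth$events[truth$events$node == ch, , drop = FALSE]
    if (nrow(ev) > 0L) {
      ev <- ev[order(ev$order), , drop = FALSE]
      for (r in seq_len(nrow(ev))) {
        params <- jsonlite::fromJSON(ev$params[r])
        arch <- apply_event(arch, ev$type[r], params)
      }
    }
    arch_at[[ch]] <- arch
  }
  tips <- list()
  for (i in seq_len(nt)) {
    tx <- tree$tip.label[i]
    tips[[tx]] <- realize_tip(arch_at[[i]], truth$cfg,
                              tip_seed(truth$cfg$seed, i), taxon = tx)$genome
  }
  tips
}

## ---------------------------------------------------------------------------
## Sequence realization

# assemble one region: spacer gene spacer gene ... spacer; returns sequence,
# feature rows (region-local 0-based) and repeat coordinate rows
assemble_region <- function(blk, arch, spacer_len, repeats_here) {
  pieces <- character(0)
  feats <- list()
  reps <- list()
  pos <- 0L
  n_slots <- nrow(blk) + 1L
  for (slot in seq_len(n_slots)) {
    sp <- random_dna(max(20L, round(runif(1, 0.6, 1.4) * spacer_len)),
                     arch$at_percent)
    rr <- repeats_here[repeats_here$slot == slot, , drop = FALSE]
    for (q in seq_len(nrow(rr))) {
      ins <- rr$ins_seq[q]
      reps[[length(reps) + 1L]] <- tibble(start = pos + nchar(sp),
                                          end = pos + nchar(sp) + nchar(ins),
                                          copy = rr$copy[q], rid = rr$rid[q])
      sp <- paste0(sp, ins)
    }
    pieces <- c(pieces, sp)
    pos <- pos + nchar(sp)
    if (slot <= nrow(blk)) {
      g <- blk$symbol[slot]
      gs <- arch$gene_seq[[g]]
      if (blk$sign[slot] == -1L) gs <- revcomp(gs)
      feats[[length(feats) + 1L]] <- tibble(
        symbol = g, strand = blk$sign[slot], start = pos,
        end = pos + nchar(gs))
      pieces <- c(pieces, gs)
      pos <- pos + nchar(gs)
    }
  }
  list(seq = paste(pieces, collapse = ""),
       feats = if (length(feats)) bind_rows(feats) else NULL,
       reps = if (length(reps)) bind_rows(reps) else NULL)
}

realize_tip <- function(arch, cfg, seed, taxon) {
  with_seed(seed, {
    gene_bp <- sum(arch$gene_len[c(arch$lsc$symbol, arch$ssc$symbol)]) +
      (if (arch$ir_present) 2L else 1L) * sum(arch$gene_len[arch$ir$symbol])
    n_spacers <- nrow(arch$lsc) + nrow(arch$ssc) +
      (if (arch$ir_present) 2L else 1L) * nrow(arch$ir) + 4L
    spacer_len <- max(30L, (cfg$genome_length_target - gene_bp) %/% n_spacers)

    prep_rep <- function(region) {
      rr <- arch$repeats[arch$repeats$region == region, , drop = FALSE]
      if (nrow(rr) == 0L) {
        return(tibble(slot = integer(), ins_seq = character(),
                      copy = integer(), rid = integer()))
      }
      bind_rows(lapply(seq_len(nrow(rr)), function(q) {
        tibble(slot = c(rr$slot1[q], rr$slot2[q]),
               ins_seq = c(rr$seq[q], if (rr$kind[q] == "palindromic")
                 revcomp(rr$seq[q]) else rr$seq[q]),
               copy = c(1L, 2L), rid = q)
      }))
    }
    n_slots_of <- function(blk) nrow(blk) + 1L
    clamp_slots <- function(rt, blk) {
      rt$slot <- pmin(rt$slot, n_slots_of(blk))
      rt
    }
    lsc_part <- assemble_region(arch$lsc, arch, spacer_len,
                                clamp_slots(prep_rep("lsc"), arch$lsc))
    ira_part <- assemble_region(arch$ir, arch, spacer_len,
                                tibble(slot = integer(), ins_seq = character(),
                                       copy = integer(), rid = integer()))
    ssc_part <- assemble_region(arch$ssc, arch, spacer_len,
                                clamp_slots(prep_rep("ssc"), arch$ssc))

    offs_lsc <- 0L
    offs_ira <- nchar(lsc_part$seq)
    offs_ssc <- offs_ira + nchar(ira_part$seq)
    if (arch$ir_present) {
      irb_seq <- revcomp(ira_part$seq)
      offs_irb <- offs_ssc + nchar(ssc_part$seq)
      seqs <- paste0(lsc_part$seq, ira_part$seq, ssc_part$seq, irb_seq)
      # keep the planted IR maximal: break complementary extension at both
      # junction pairs by editing one spacer base
      seqs <- break_ir_extension(seqs, offs_ira, offs_ssc, offs_irb,
                                 nchar(irb_seq))
      ir <- structure(list(ira = c(offs_ira, offs_ssc),
                           irb = c(offs_irb, offs_irb + nchar(irb_seq)),
                           lsc = c(offs_irb + nchar(irb_seq), nchar(seqs) + offs_ira),
                           ssc = c(offs_ssc, offs_irb),
                           ir_len = nchar(ira_part$seq),
                           genome_length = nchar(seqs)),
                      class = "ir_annotation")
      # LSC wraps the origin in coordinates; normalize: lsc = [irb_end, L) + [0, ira_start)
      ir$lsc <- c(ir$irb[2] %% nchar(seqs), offs_ira + nchar(seqs))
      if (ir$lsc[1] == 0L) ir$lsc <- c(0L, offs_ira)
    } else {
      seqs <- paste0(lsc_part$seq, ira_part$seq, ssc_part$seq)
      ir <- NULL
    }
    feats <- bind_rows(
      mutate(lsc_part$feats, start = .data$start + offs_lsc,
             end = .data$end + offs_lsc),
      mutate(ira_part$feats, start = .data$start + offs_ira,
             end = .data$end + offs_ira),
      mutate(ssc_part$feats, start = .data$start + offs_ssc,
             end = .data$end + offs_ssc))
    if (arch$ir_present && !is.null(ira_part$feats)) {
      A0 <- offs_ira; A1 <- offs_ssc; B0 <- ir$irb[1]
      irb_feats <- ira_part$feats |>
        mutate(start0 = B0 + (A1 - A0) - (.data$end + offs_ira - A0),
               end0 = B0 + (A1 - A0) - (.data$start + offs_ira - A0),
               strand = -.data$strand) |>
        mutate(start = .data$start0, end = .data$end0) |>
        select("symbol", "strand", "start", "end")
      feats <- bind_rows(feats, irb_feats)
    }
    feats <- feats |> arrange(.data$start) |>
      mutate(feature_id = row_number(), raw_name = .data$symbol,
             kind = dplyr::case_when(
               .data$symbol %in% c("rrs", "rrl", "rrf") ~ "rRNA",
               startsWith(.data$symbol, "trn") ~ "tRNA",
               TRUE ~ "CDS"),
             part_index = 1L, intron_type = NA_character_) |>
      select("feature_id", "raw_name", "symbol", "kind", "strand",
             "start", "end", "part_index", "intron_type")
    if (!is.null(cfg$fragment)) {
      feats <- fragment_feature(feats, cfg$fragment)
    }
    genome <- plastome(taxon = taxon, sequence = seqs, features = feats,
                       accession = "", circular = TRUE, complete = TRUE)
    ord <- collapsed_order(arch, taxon)
    list(genome = genome, ir = ir, order = ord)
  })
}

# edit one base where a complementary extension would lengthen the planted IR
break_ir_extension <- function(seqs, A0, A1, B0, irb_len) {
  L <- nchar(seqs)
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  pick_other <- function(b, avoid) setdiff(c("A", "C", "G", "T"), c(b, avoid))[1]
  # outward extension at (A0-1, B1): bases must not be complementary
  b1_pos <- (B0 + irb_len) %% L + 1L  # 1-based position after IRB
  a_left <- substr(seqs, A0, A0)      # 1-based base before IRA
  if (comp1(a_left) == substr(seqs, b1_pos, b1_pos)) {
    substr(seqs, b1_pos, b1_pos) <- pick_other(substr(seqs, b1_pos, b1_pos),
                                               comp1(a_left))
  }
  # outward extension at (A1, B0-1)
  a_right <- substr(seqs, A1 + 1L, A1 + 1L)  # first base after IRA
  if (comp1(a_right) == substr(seqs, B0, B0)) {
    substr(seqs, A1 + 1L, A1 + 1L) <- pick_other(a_right, comp1(substr(seqs, B0, B0)))
  }
  seqs
}

fragment_feature <- function(feats, fragment) {
  sym <- fragment$symbol; parts <- fragment$parts
  idx <- which(feats$symbol == sym)[1]
  if (is.na(idx)) return(feats)
  row <- feats[idx, , drop = FALSE]
  len <- row$end - row$start
  cuts <- round(seq(0, len, length.out = parts + 1L))
  pieces <- lapply(seq_len(parts), function(p) {
    r <- row
    r$start <- row$start + cuts[p]
    r$end <- row$start + cuts[p + 1L]
    r$part_index <- p
    r$raw_name <- paste0(sym, "_part", p)
    r
  })
  out <- bind_rows(feats[-idx, , drop = FALSE], bind_rows(pieces)) |>
    arrange(.data$start) |> mutate(feature_id = row_number())
  out
}

# collapsed circular signed order (one IR copy), clockwise from origin
collapsed_order <- function(arch, taxon) {
  blk <- bind_rows(arch$lsc, arch$ir, arch$ssc)
  new_gene_order(tibble(taxon = taxon, position = seq_len(nrow(blk)),
                        symbol = blk$symbol, sign = blk$sign), circular = TRUE)
}

#' Apply k random inversions to a gene order
#'
#' Utility for parameter-recovery experiments: applies `k` independent
#' inversions with uniformly chosen segment endpoints to a circular signed
#' gene order (segments never wrap the linearization origin, without loss of
#' generality for distance computations).
#'
#' @param o A `gene_order` tibble for one taxon.
#' @param k Number of inversions.
#' @return The rearranged `gene_order`.
#' @export
random_inversions <- function(o, k) {
  o <- o[order(o$position), , drop = FALSE]
  n <- nrow(o)
  sym <- o$symbol; sgn <- o$sign
  for (t in seq_len(k)) {
    ij <- sort(sample(n, 2L))
    i <- ij[1]; j <- ij[2]
    idx <- i:j
    sym[idx] <- rev(sym[idx])
    sgn[idx] <- -rev(sgn[idx])
  }
  new_gene_order(tibble(taxon = o$taxon[1], position = seq_len(n),
                        symbol = sym, sign = sgn),
                 circular = is_circular_order(o))
}

#' Write simulated tips as GenBank + FASTA fixtures
#'
#' @param truth A `truth_log`.
#' @param dir Output directory (created if needed).
#' @return Tibble of written paths.
#' @export
write_sim_bundle <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(truth$tips), function(tx) {
    gb <- file.path(dir, paste0(tx, ".gb"))
    fa <- file.path(dir, paste0(tx, ".fasta"))
    write_genbank(truth$tips[[tx]], gb)
    write_fasta(setNames(truth$tips[[tx]]$sequence, tx), fa)
    tibble(taxon = tx, genbank = gb, fasta = fa)
  })
  ape::write.tree(truth$tree, file.path(dir, "tree.nwk"))
  write.table(truth$events, file.path(dir, "truth_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(truth$cfg)[setdiff(names(truth$cfg), "fragment")],
                       file.path(dir, "sim_config.json"), auto_unbox = TRUE)
  bind_rows(rows)
}
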