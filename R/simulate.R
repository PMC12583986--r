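# evaluate code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Mutate a protein towards a target percent similarity
#'
#' Substitutes residues of the reference with amino acids scoring
#' non-positively against the original (so each substituted column counts as
#' a non-positive column), choosing the number of substituted positions by
#' bisection against the realized similarity measured with
#' \code{\link{align_local}}. For references of a few hundred residues the
#' realized similarity lands within a few points of the target.
#'
#' @param reference a \code{\link{protein_record}} (or sequence string)
#' @param target_similarity percent in (0, 100]
#' @param seed integer seed (explicit; no global random state is consumed)
#' @param scoring a \code{\link{scoring_scheme}}
#' @return a \code{protein_record} with attribute \code{realized_similarity}
#' @export
mutate_protein <- function(reference, target_similarity, seed,
                           scoring = scoring_scheme()) {
  if (!is.numeric(target_similarity) || target_similarity <= 0 ||
      target_similarity > 100)
    stop("target_similarity must lie in (0, 100]")
  refseq <- .as_aa(reference)
  id <- if (inherits(reference, "protein_record")) reference$id else "ref"
  out_id <- sprintf("%s_sim%g", id, target_similarity)
  if (target_similarity == 100)
    return(structure(protein_record(out_id, refseq),
                     realized_similarity = 100))
  sub <- scoring$matrix
  res <- strsplit(refseq, "")[[1]]
  n <- length(res)
  with_seed(seed, {
    perm <- sample.int(n)
    repl <- vapply(res[perm], function(a) {
      pool <- .aa20[sub[a, .aa20] <= 0 & .aa20 != a]
      if (!length(pool)) pool <- .aa20[.aa20 != a]
      sample(pool, 1)
    }, character(1))
    mutant <- function(k) {
      s <- res
      if (k > 0) s[perm[seq_len(k)]] <- repl[seq_len(k)]
      paste(s, collapse = "")
    }
    measure <- function(k)
      align_local(refseq, mutant(k), scoring)$percent_similarity
    # realized similarity decreases in the substitution count; a first guess
    # at the naive proportion is refined by a few guided corrections
    k <- max(0L, min(n, round(n * (1 - target_similarity / 100))))
    best_k <- k
    best_err <- abs(measure(k) - target_similarity)
    sim <- target_similarity + sign(best_err)  # force one correction pass
    for (it in 1:4) {
      if (best_err <= 1) break
      sim <- measure(k)
      err <- abs(sim - target_similarity)
      if (err < best_err) { best_err <- err; best_k <- k }
      step <- round(n * (sim - target_similarity) / 100 * 0.9)
      if (step == 0) step <- sign(sim - target_similarity)
      k <- max(0L, min(n, k + step))
    }
    structure(protein_record(out_id, mutant(best_k)),
              realized_similarity = measure(best_k))
  })
}

#' Genotype scenario for genome simulation
#'
#' @param families_present catalog families planted in the genome
#' @param fragments number of pieces the canonical cluster is split into
#' @param n_decoys number of planted sub-threshold shc decoys
#' @param target_similarity percent similarity of planted genes to the
#'   query proteins
#' @param decoy_similarity percent similarity of decoys (below the secondary
#'   Shc floor)
#' @param n_background background (non-pathway) gene count
#' @param n_contigs contig count
#' @return a \code{genotype_scenario} list
#' @export
genotype_scenario <- function(families_present,
                              fragments = 1L, n_decoys = 0L,
                              target_similarity = 85,
                              decoy_similarity = 35,
                              n_background = 300L, n_contigs = 2L) {
  stopifnot(fragments >= 1, n_contigs >= 1, n_background >= 0)
  structure(list(families_present = families_present,
                 fragments = as.integer(fragments),
                 n_decoys = as.integer(n_decoys),
                 target_similarity = target_similarity,
                 decoy_similarity = decoy_similarity,
                 n_background = as.integer(n_background),
                 n_contigs = as.integer(n_contigs)),
            class = "genotype_scenario")
}

#' Simulate an annotated genome with a planted hpn genotype
#'
#' Emits a proteome and a matching gene feature table in which the canonical
#' hpn cluster genes of the scenario lie in canonical order (optionally split
#' into fragments and strand-flipped per fragment), non-cluster pathway genes
#' are scattered, background genes are residue-shuffled copies of the
#' reference proteins, and optional squalene-hopene cyclase decoys are
#' planted below the secondary-Shc similarity floor. Locus tags step by 5
#' along each contig.
#'
#' @param scenario a \code{\link{genotype_scenario}}
#' @param seed integer seed
#' @param catalog a \code{gene_catalog}
#' @param references query proteins (defaults to the shipped surrogates)
#' @return list with \code{proteome} (\code{AAStringSet} named by locus tag),
#'   \code{features} (data frame: contig, start, end, strand, locus_tag),
#'   \code{truth} (\code{simulation_truth}: planted presence map, planted
#'   protein locus tags, decoy tags, expected chemotype, seed)
#' @export
simulate_genome <- function(scenario, seed, catalog = load_gene_catalog(),
                            references = load_reference_proteins()) {
  fams <- scenario$families_present
  unknown <- setdiff(fams, catalog$family_id)
  if (length(unknown)) stop("unknown families: ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    canon <- catalog[catalog$canonical_bgc_member, ]
    canon <- canon[order(canon$canonical_order), ]
    bgc_fams <- intersect(canon$family_id, fams)
    other_fams <- setdiff(fams, bgc_fams)

    make_planted <- function(fam, i) {
      qlab <- catalog$query_label[match(fam, catalog$family_id)]
      ref <- protein_record(qlab, as.character(references[[qlab]]))
      if (scenario$target_similarity >= 100) ref
      else mutate_protein(ref, scenario$target_similarity,
                          seed = seed + 1000L + i)
    }
    planted <- lapply(seq_along(fams),
                      function(i) make_planted(fams[i], i))
    names(planted) <- fams
    decoys <- lapply(seq_len(scenario$n_decoys), function(i) {
      ref <- protein_record("REF_SHC", as.character(references[["REF_SHC"]]))
      mutate_protein(ref, scenario$decoy_similarity, seed = seed + 2000L + i)
    })
    bg <- lapply(seq_len(scenario$n_background), function(i) {
      src <- sample(length(references), 1)
      paste(sample(strsplit(as.character(references[[src]]), "")[[1]]),
            collapse = "")
    })

    # fragment the cluster run; each fragment keeps canonical internal order
    frag_n <- min(scenario$fragments, max(length(bgc_fams), 1L))
    frag_of <- if (length(bgc_fams))
      sort(rep_len(seq_len(frag_n), length(bgc_fams))) else integer(0)
    fragments <- split(bgc_fams, frag_of)

    # distribute slots: fragments and singles over contigs, background fills
    n_ctg <- scenario$n_contigs
    slots <- vector("list", n_ctg)          # per contig: list of gene specs
    spacer <- 12L                           # background genes that break both
                                            # the intervening-gene and the
                                            # locus-gap adjacency rules
    gene_spec <- function(kind, fam = NA, seq, strand = "+")
      list(kind = kind, fam = fam, seq = seq, strand = strand)
    bg_pool <- bg
    take_bg <- function(k) {
      k <- min(k, length(bg_pool))
      out <- bg_pool[seq_len(k)]
      bg_pool <<- bg_pool[-seq_len(k)]
      out
    }
    for (fi in seq_along(fragments)) {
      ctg <- ((fi - 1L) %% n_ctg) + 1L
      flip <- stats::runif(1) < 0.5
      fam_run <- fragments[[fi]]
      if (flip) fam_run <- rev(fam_run)
      run <- lapply(fam_run, function(f)
        gene_spec("pathway", f, planted[[f]]$sequence,
                  strand = if (flip) "-" else "+"))
      if (length(slots[[ctg]]))
        slots[[ctg]] <- c(slots[[ctg]],
                          lapply(take_bg(spacer), function(s) gene_spec("bg", seq = s)))
      slots[[ctg]] <- c(slots[[ctg]], run)
    }
    for (f in other_fams) {
      ctg <- sample(n_ctg, 1)
      slots[[ctg]] <- c(slots[[ctg]],
                        lapply(take_bg(spacer), function(s) gene_spec("bg", seq = s)),
                        list(gene_spec("pathway", f, planted[[f]]$sequence)))
    }
    for (d in seq_along(decoys)) {
      ctg <- sample(n_ctg, 1)
      slots[[ctg]] <- c(slots[[ctg]],
                        lapply(take_bg(spacer), function(s) gene_spec("bg", seq = s)),
                        list(gene_spec("decoy", "shc_decoy", decoys[[d]]$sequence)))
    }
    # remaining background distributed round-robin at contig ends
    rem <- bg_pool; bg_pool <- list()
    for (i in seq_along(rem)) {
      ctg <- ((i - 1L) %% n_ctg) + 1L
      slots[[ctg]] <- c(slots[[ctg]], list(gene_spec("bg", seq = rem[[i]])))
    }

    seqs <- character(0); tags <- character(0)
    feat <- list(); truth_tags <- character(0); decoy_tags <- character(0)
    for (ctg in seq_len(n_ctg)) {
      pos <- 1L
      for (i in seq_along(slots[[ctg]])) {
        g <- slots[[ctg]][[i]]
        tag <- sprintf("SIM%d_%05d", ctg, 5L * i)
        glen <- 3L * nchar(g$seq) + 3L
        feat[[length(feat) + 1L]] <- data.frame(
          contig = paste0("contig_", ctg), start = pos,
          end = pos + glen - 1L, strand = g$strand, locus_tag = tag,
          stringsAsFactors = FALSE)
        pos <- pos + glen + 100L
        seqs <- c(seqs, g$seq); tags <- c(tags, tag)
        if (g$kind == "pathway") truth_tags[g$fam] <- tag
        if (g$kind == "decoy") decoy_tags <- c(decoy_tags, tag)
      }
    }
    proteome <- Biostrings::AAStringSet(seqs)
    names(proteome) <- tags
    presence <- stats::setNames(
      ifelse(catalog$family_id %in% fams, "present", "absent"),
      catalog$family_id)
    truth <- structure(list(
      presence = presence, planted_tags = truth_tags,
      decoy_tags = decoy_tags, fragments = frag_n,
      target_similarity = scenario$target_similarity,
      chemotype = predict_chemotype(genotype("sim", presence)),
      seed = seed), class = "simulation_truth")
    list(proteome = proteome,
         features = do.call(rbind, feat),
         truth = truth)
  })
}

#' Simulate LC and GC-MRM measurements for a chemotype
#'
#' Draws a BHPD inventory restricted to the structure classes the chemotype
#' permits (abundances from a symmetric Dirichlet), derives the implied GC
#' hopanol profile by in-silico Rohmer degradation, and emits peak tables
#' with multiplicative lognormal noise (the standard noise model for
#' chromatographic peak areas). Ring-A methylated MRM peaks are planted at
#' the given degrees of methylation and the 22S/22R split of the C32 hopanol
#' at the given epimer percentage; \code{noise_cv = 0} reproduces the planted
#' values exactly.
#'
#' @param chemotype a \code{\link{predict_chemotype}} prediction
#' @param seed integer seed
#' @param noise_cv coefficient of variation of the lognormal peak noise
#' @param me2_degree_pct,me3_degree_pct planted degrees of ring-A methylation
#'   (percent) applied when the chemotype has the corresponding capacity
#' @param s22_pct planted 22S/(22S+22R) percentage for extended hopanols
#' @param total_conc_mg_g planted summed BHPD concentration (mg per g cells)
#' @param biomass_g simulated dry biomass (g)
#' @param is_area internal-standard peak area
#' @param is_mass_mg internal-standard mass (mg)
#' @param dirichlet_alpha symmetric Dirichlet concentration
#' @return list with \code{lc_inventory} (data frame structure_id/response),
#'   \code{gc_peaks} (data frame analyte/precursor_mz/product_mz/area),
#'   \code{truth} (\code{simulation_truth}: true inventory, degrees,
#'   epimer fraction, concentration, seed)
#' @export
simulate_lipidome <- function(chemotype, seed, noise_cv = 0.05,
                              me2_degree_pct = 1.0, me3_degree_pct = 0.2,
                              s22_pct = 0, total_conc_mg_g = 5,
                              biomass_g = 0.02, is_area = 1e6,
                              is_mass_mg = 0.03075,
                              dirichlet_alpha = 1) {
  if (!isTRUE(chemotype$bhpd_any) && !isTRUE(chemotype$c30_hopanoids))
    stop("chemotype permits no hopanoid production; nothing to simulate")
  pool <- list()
  add <- function(id, ...) pool[[id]] <<- bhpd_structure(..., structure_id = id)
  if (isTRUE(chemotype$bhpd_any))
    add("Ia", "nucleoside", subtype = "adenosyl", c22_config = "R")
  if (isTRUE(chemotype$bht)) add("IIa", "tetrol", c22_config = "R")
  if (isTRUE(chemotype$aminotriol))
    add("Va", "amino", subtype = "aminotriol", c22_config = "R")
  if (isTRUE(chemotype$ce_acetylglucosamine_terminal))
    add("IIIa", "ce_series", base = "tetrol", stage = "acetylglucosamine",
        c22_config = "R")
  if (isTRUE(chemotype$ce_glucosamine_terminal)) {
    add("IIIa", "ce_series", base = "tetrol", stage = "acetylglucosamine",
        c22_config = "R")
    add("IIIb", "ce_series", base = "tetrol", stage = "glucosamine",
        c22_config = "R")
  }
  if (isTRUE(chemotype$ce_terminal)) {
    add("IIIb", "ce_series", base = "tetrol", stage = "glucosamine",
        c22_config = "R")
    add("IIIc", "ce_series", base = "tetrol", stage = "cyclitol",
        c22_config = "R")
  }
  if (!length(pool))
    stop("chemotype permits C30 hopanoids only; no BHPD inventory to draw")
  with_seed(seed, {
    w <- stats::rgamma(length(pool), shape = dirichlet_alpha)
    ab <- 100 * w / sum(w)
    inv <- normalize_inventory(unname(pool), ab)
    lnoise <- function(n) {
      if (noise_cv == 0) return(rep(1, n))
      sdl <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    lc <- data.frame(structure_id = inv$structure_id,
                     response = inv$rel_abundance * lnoise(nrow(inv)),
                     stringsAsFactors = FALSE)

    gc <- predict_gc_profile(inv)
    visible <- 100 - attr(gc, "invisible_fraction")
    total_area <- total_conc_mg_g * biomass_g / is_mass_mg * is_area
    peaks <- list()
    peak <- function(analyte, prec, prod, area)
      peaks[[length(peaks) + 1L]] <<- data.frame(
        analyte = analyte, precursor_mz = prec, product_mz = prod,
        area = area, stringsAsFactors = FALSE)
    peak("IS_n-tricosan-1-ol", NA_real_, NA_real_, is_area)
    d2 <- if (isTRUE(chemotype$methyl_2)) me2_degree_pct else 0
    d3 <- if (isTRUE(chemotype$methyl_3)) me3_degree_pct else 0
    prec_mz <- c(`30` = 500.5, `31` = 514.5, `32` = 528.5)
    if (nrow(gc)) for (cn in unique(gc$carbon_number)) {
      share <- sum(gc$share[gc$carbon_number == cn])
      u_area <- total_area * (visible / 100) * share / 100
      nm <- paste0("c", cn, "_hopanol")
      if (cn == 32L && s22_pct > 0) {
        peak(paste0(nm, "_22S"), prec_mz[["32"]], 191,
             u_area * s22_pct / 100 * lnoise(1))
        peak(paste0(nm, "_22R"), prec_mz[["32"]], 191,
             u_area * (1 - s22_pct / 100) * lnoise(1))
      } else {
        peak(nm, prec_mz[[as.character(cn)]], 191, u_area * lnoise(1))
      }
      if (d2 > 0)
        peak(paste0("2me_", nm), prec_mz[[as.character(cn)]] + 14, 205,
             u_area * d2 / (100 - d2) * lnoise(1))
      if (d3 > 0)
        peak(paste0("3me_", nm), prec_mz[[as.character(cn)]] + 14, 205,
             u_area * d3 / (100 - d3) * lnoise(1))
    }
    truth <- structure(list(
      inventory = inv, gc_profile = gc,
      me2_degree_pct = d2, me3_degree_pct = d3, s22_pct = s22_pct,
      total_conc_mg_g = total_conc_mg_g, biomass_g = biomass_g,
      noise_cv = noise_cv, seed = seed,
      chemotype = chemotype), class = "simulation_truth")
    list(lc_inventory = lc, gc_peaks = do.call(rbind, peaks), truth = truth)
  })
}
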