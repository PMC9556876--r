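# Self-contained synthetic worlds with planted functional structure: a
# planted-partition PPI network whose modules carry private GO terms,
# module-biased sequence composition, module-specific domains and
# domain-domain interactions, and held-out targets with known truth. Every
# pipeline stage is testable offline against the planted labels.

# Residue signatures that push modules apart in physico-chemical space
# (chromophores, acidic, basic, aliphatic, ...).
MODULE_SIGNATURES <- list(
  c("W", "Y"), c("D", "E"), c("K", "R"), c("I", "V"),
  c("F", "L"), c("S", "T"), c("G", "P"), c("M", "C")
)

#' Generate a synthetic world
#'
#' Builds a planted-partition weighted network (`n_modules` modules of
#' `module_size` nodes; within-module edge probability `p_in`, between
#' `p_out`; within-module weights drawn from `Beta(weight_in)`, between from
#' `Beta(weight_out)`), gives each module `terms_per_module` private GO
#' terms annotated to all members (a fraction `annotation_noise` of
#' annotations is rewired to another module's terms), samples sequences from
#' a module-biased amino-acid composition, assigns module-private domains
#' with within-module DDIs and domain-to-GO links, and holds out a fraction
#' of nodes as prediction targets whose annotations are moved to the truth.
#'
#' @param n_modules number of modules (default 4).
#' @param module_size proteins per module (default 25).
#' @param p_in,p_out within- / between-module edge probabilities
#'   (default 0.3 / 0.02; `p_in > p_out` required).
#' @param weight_in,weight_out Beta shape pairs for edge weights (defaults
#'   `c(8, 2)` and `c(2, 8)`, i.e. mean 0.8 within vs 0.2 between).
#' @param terms_per_module private GO terms per module (default 10, aspects
#'   cycled BP/MF/CC). Ten terms per protein matches realistic annotation
#'   density; the resulting vocabulary also keeps chance-level recovery
#'   (with top-10 predictors) well below any planted signal.
#' @param annotation_noise fraction of annotations rewired across modules
#'   (default 0.05; must be `< 0.5`).
#' @param seq_length sequence length (default 150).
#' @param composition_shift extra probability mass moved onto the module's
#'   signature residues (default 0.5).
#' @param domains_per_module private domains per module (default 2).
#' @param holdout_fraction fraction of proteins held out as targets
#'   (default 0.1). Held-out proteins are unannotated for every predictor;
#'   a unanimous consensus is structurally impossible for a target whose
#'   physico-chemically nearest cluster mate is itself held out, so large
#'   holdouts cap the achievable recovery at roughly one minus the holdout.
#' @param seed integer seed; worlds are reproducible from (params, seed).
#' @return object of class `synthetic_world`: list with `network`,
#'   `annotations`, `sequences`, `domain_tables`, `idmap`, `truth`,
#'   `term_aspects`, `modules` and `params`.
#' @export
generate_world <- function(n_modules = 4, module_size = 25, p_in = 0.3,
                           p_out = 0.02, weight_in = c(8, 2),
                           weight_out = c(2, 8), terms_per_module = 10,
                           annotation_noise = 0.05, seq_length = 150,
                           composition_shift = 0.5, domains_per_module = 2,
                           holdout_fraction = 0.1, seed = 1L) {
  if (p_in <= p_out) stopf("generate_world: need p_in > p_out")
  if (annotation_noise < 0 || annotation_noise >= 0.5) {
    stopf("generate_world: annotation_noise must be in [0, 0.5)")
  }
  if (n_modules < 1 || module_size < 2) {
    stopf("generate_world: modules must have at least 2 proteins")
  }
  n <- n_modules * module_size
  if (ceiling(holdout_fraction * n) < 1) {
    stopf("generate_world: holdout_fraction yields no targets")
  }
  params <- list(n_modules = n_modules, module_size = module_size,
                 p_in = p_in, p_out = p_out, weight_in = weight_in,
                 weight_out = weight_out, terms_per_module = terms_per_module,
                 annotation_noise = annotation_noise, seq_length = seq_length,
                 composition_shift = composition_shift,
                 domains_per_module = domains_per_module,
                 holdout_fraction = holdout_fraction, seed = seed)
  with_seed(seed, {
    ids <- sprintf("P%03d", seq_len(n))
    modules <- stats::setNames(rep(seq_len(n_modules), each = module_size),
                               ids)

    # planted-partition network
    pairs <- utils::combn(ids, 2)
    same <- modules[pairs[1, ]] == modules[pairs[2, ]]
    prob <- ifelse(same, p_in, p_out)
    keep <- stats::runif(length(prob)) < prob
    wts <- numeric(sum(keep))
    in_kept <- same[keep]
    wts[in_kept] <- stats::rbeta(sum(in_kept), weight_in[1], weight_in[2])
    wts[!in_kept] <- stats::rbeta(sum(!in_kept), weight_out[1], weight_out[2])
    edges <- data.frame(a = pairs[1, keep], b = pairs[2, keep], weight = wts,
                        stringsAsFactors = FALSE)
    network <- ppi_graph(edges)
    # isolated proteins stay in the network as vertices
    network <- igraph::add_vertices(
      network, length(setdiff(ids, igraph::V(network)$name)),
      name = setdiff(ids, igraph::V(network)$name))

    # module-private GO terms, annotated to every member, then noised
    aspects <- c("BP", "MF", "CC")
    term_ids <- sprintf("GO:%07d", seq_len(n_modules * terms_per_module))
    term_module <- rep(seq_len(n_modules), each = terms_per_module)
    term_aspects <- stats::setNames(
      aspects[(seq_along(term_ids) - 1L) %% 3L + 1L], term_ids)
    ann <- do.call(rbind, lapply(ids, function(p) {
      data.frame(protein_id = p,
                 go_id = term_ids[term_module == modules[[p]]],
                 stringsAsFactors = FALSE)
    }))
    rewire <- stats::runif(nrow(ann)) < annotation_noise
    for (i in which(rewire)) {
      other <- term_ids[term_module != modules[[ann$protein_id[i]]]]
      ann$go_id[i] <- sample(other, 1L)
    }
    ann$aspect <- term_aspects[ann$go_id]
    annotations <- annotation_table(ann)

    # module-biased sequences
    sequences <- vapply(ids, function(p) {
      sig <- MODULE_SIGNATURES[[(modules[[p]] - 1L) %%
                                  length(MODULE_SIGNATURES) + 1L]]
      prob <- stats::setNames(rep((1 - composition_shift) / 20, 20),
                              AA_ALPHABET)
      prob[sig] <- prob[sig] + composition_shift / length(sig)
      paste(sample(AA_ALPHABET, seq_length, replace = TRUE, prob = prob),
            collapse = "")
    }, "")

    # module-private domains, within-module DDIs, domain -> module terms
    pd <- do.call(rbind, lapply(ids, function(p) {
      data.frame(protein_id = p,
                 domain_id = sprintf("DM%02d_%d", modules[[p]],
                                     seq_len(domains_per_module)),
                 stringsAsFactors = FALSE)
    }))
    ddi <- do.call(rbind, lapply(seq_len(n_modules), function(m) {
      doms <- sprintf("DM%02d_%d", m, seq_len(domains_per_module))
      if (length(doms) < 2L) return(data.frame(a = doms, b = doms))
      t(utils::combn(doms, 2)) |> as.data.frame(stringsAsFactors = FALSE) |>
        stats::setNames(c("a", "b"))
    }))
    dg <- do.call(rbind, lapply(seq_len(n_modules), function(m) {
      expand.grid(domain_id = sprintf("DM%02d_%d", m,
                                      seq_len(domains_per_module)),
                  go_id = term_ids[term_module == m],
                  stringsAsFactors = FALSE)
    }))
    dt <- domain_tables(pd, ddi, dg)

    map <- idmap(ids, ids, "network->annotation (identity)")

    # hold out targets: their annotations are removed from the table and the
    # planted module terms (not the noisy observations) become the truth
    targets <- sort(sample(ids, ceiling(holdout_fraction * n)))
    ho <- holdout_annotations(annotations, targets)
    ho$truth <- lapply(stats::setNames(targets, targets), function(p) {
      sort(term_ids[term_module == modules[[p]]])
    })

    structure(list(network = network, annotations = ho$table,
                   sequences = sequences, domain_tables = dt, idmap = map,
                   truth = ho$truth, term_aspects = term_aspects,
                   modules = modules, params = params),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic world: %d proteins in %d modules, %d edges, %d annotations, %d targets (seed %d)\n",
    length(x$sequences), x$params$n_modules,
    igraph::ecount(x$network), nrow(x$annotations), length(x$truth),
    x$params$seed))
  invisible(x)
}

#' Write a world to disk
#'
#' Emits every format the readers consume: `network.tsv`, `annotations.tsv`,
#' `sequences.fasta`, `protein_domains.tsv`, `ddi.tsv`, `domain_go.tsv`,
#' `idmap.tsv`, `truth.tsv` and `params.json`. The truth file never leaks
#' into the annotations file.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_edge_list(world$network, fp("network.tsv"))
  write_annotations(world$annotations, fp("annotations.tsv"))
  write_fasta(world$sequences, fp("sequences.fasta"))
  write_domain_tables(world$domain_tables, fp("protein_domains.tsv"),
                      fp("ddi.tsv"), fp("domain_go.tsv"))
  write_mapping(world$idmap, fp("idmap.tsv"))
  truth <- data.frame(
    target = rep(names(world$truth), lengths(world$truth)),
    go_id = unlist(world$truth, use.names = FALSE),
    stringsAsFactors = FALSE)
  truth$aspect <- world$term_aspects[truth$go_id]
  utils::write.table(truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(world$params, fp("params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a world back from disk
#'
#' Inverse of [write_world()]; sequence-free fields (`modules`) are not
#' stored on disk and come back `NULL`.
#'
#' @param dir directory written by [write_world()].
#' @return a `synthetic_world` (without `modules`).
#' @export
read_world <- function(dir) {
  fp <- function(f) file.path(dir, f)
  truth_df <- utils::read.delim(fp("truth.tsv"), stringsAsFactors = FALSE)
  truth <- lapply(split(truth_df$go_id, truth_df$target), function(x)
    sort(unique(x)))
  term_aspects <- stats::setNames(truth_df$aspect, truth_df$go_id)
  ann <- read_annotations(fp("annotations.tsv"))
  ta <- stats::setNames(ann$aspect, ann$go_id)
  term_aspects <- c(term_aspects, ta[setdiff(names(ta), names(term_aspects))])
  term_aspects <- term_aspects[!duplicated(names(term_aspects))]
  structure(list(
    network = read_edge_list(fp("network.tsv")),
    annotations = ann,
    sequences = read_fasta(fp("sequences.fasta")),
    domain_tables = read_domain_tables(fp("protein_domains.tsv"),
                                       fp("ddi.tsv"), fp("domain_go.tsv")),
    idmap = read_mapping(fp("idmap.tsv")),
    truth = truth,
    term_aspects = term_aspects,
    modules = NULL,
    params = jsonlite::read_json(fp("params.json"), simplifyVector = TRUE)
  ), class = "synthetic_world")
}
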