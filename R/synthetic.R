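#' Synthetic-study generator configuration
#'
#' Parameters controlling the synthetic ontology, annotation, pathway and
#' disease fixtures. The defaults define the standard fixture `std-v1`: a
#' desk-scale emulation of the statistical shape of real pathway/ontology
#' collections — a rooted DAG with two relation types, multi-term gene
#' annotations with an IEA-only stratum, heavily overlapping long-tailed
#' pathway sets with exact duplicates, disease-named decoy pathways and
#' sub-enrichment-size pathways, plus planted (functionally concentrated) and
#' null diseases.
#'
#' @param seed Master seed; every generator stage derives its own stream
#'   from it, so identical configs regenerate byte-identical files.
#' @param n_terms Ontology size including the root (default 60).
#' @param n_branches Children of the root; one per pathway theme. The default
#'   4 mirrors the handful of major functional domains (metabolism,
#'   signaling, immunity, DNA processes) a global pathway collection
#'   organizes into.
#' @param dag_extra_edge_prob Probability a non-root term gets a second
#'   parent, turning the tree into a DAG (default 0.08).
#' @param part_of_fraction Fraction of edges labeled `part_of` (default 0.15).
#' @param n_genes Number of genes (default 400).
#' @param terms_per_gene Mean direct annotations per gene (default 3). Real
#'   genomes average ~8 direct Biological Process terms against an ontology
#'   of >10,000 terms; at a 60-term scale the annotation *density* is what
#'   must be preserved, or every term saturates and no term is specific.
#' @param home_branch_bias Fraction of a gene's direct annotations lying in
#'   its home branch; the rest is ontology-wide noise (default 0.9, the
#'   coherence curated annotation sets show).
#' @param iea_fraction Fraction of genes whose annotations are all IEA, hence
#'   lost when evidence is filtered (default 0.12).
#' @param n_themes Number of pathway themes; must not exceed `n_branches`
#'   (default 4).
#' @param pathways_per_theme Pathways generated per theme (default 20).
#' @param pathway_size_median Target median pathway size (default 23).
#' @param pathway_size_sdlog Log-scale spread of pathway sizes; gives the
#'   long upper tail (default 0.6).
#' @param duplicate_fraction Fraction of pathways copied verbatim under a new
#'   id (default 0.1).
#' @param overlap_inflation Fraction of each pathway filled from its theme's
#'   small core gene set; drives mean pathway memberships per gene up
#'   (default 0.3).
#' @param crosstalk_fraction Fraction of each theme's pathways that draw
#'   their genes from two adjacent themes (default 0.1). These cross-talk
#'   pathways keep the pruned network connected across its functional
#'   modules, as bridging pathways do in real collections.
#' @param n_disease_named Decoy pathways named after diseases, drugs and
#'   addictions (default 6, two per category).
#' @param n_tiny Pathways of size 3, below the enrichment floor (default 2).
#' @param n_planted_diseases Diseases whose genes concentrate in 3-6 pathways
#'   of one theme (default 8).
#' @param n_null_diseases Diseases whose genes are uniform draws from the
#'   pathway gene universe (default 8).
#' @param genes_per_disease Genes per disease (default 45, the scale of a
#'   well-annotated multi-process disorder; each of the 4-6 perturbed
#'   pathways must show an overlap large enough to enrich).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 17L,
                         n_terms = 60L,
                         n_branches = 4L,
                         dag_extra_edge_prob = 0.08,
                         part_of_fraction = 0.15,
                         n_genes = 400L,
                         terms_per_gene = 3,
                         home_branch_bias = 0.9,
                         iea_fraction = 0.12,
                         n_themes = 4L,
                         pathways_per_theme = 20L,
                         pathway_size_median = 23L,
                         pathway_size_sdlog = 0.6,
                         duplicate_fraction = 0.1,
                         overlap_inflation = 0.3,
                         crosstalk_fraction = 0.1,
                         n_disease_named = 6L,
                         n_tiny = 2L,
                         n_planted_diseases = 8L,
                         n_null_diseases = 8L,
                         genes_per_disease = 45L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_terms >= 5L, cfg$n_themes <= cfg$n_branches,
            cfg$part_of_fraction >= 0, cfg$part_of_fraction <= 1,
            cfg$iea_fraction >= 0, cfg$iea_fraction <= 1,
            cfg$duplicate_fraction >= 0, cfg$duplicate_fraction <= 1,
            cfg$overlap_inflation >= 0, cfg$overlap_inflation <= 1)
  structure(cfg, class = "synth_config")
}

synth_term_id <- function(i) sprintf("GO:SYN%04d", i)
synth_gene_id <- function(i) sprintf("G%04d", i)

#' Generate a synthetic OBO ontology
#'
#' A rooted random DAG: a tree grown under `n_branches` root children, plus
#' extra cross-edges (always toward lower-index terms, so acyclicity is
#' guaranteed by construction), with a fraction of edges labeled `part_of`.
#'
#' @param cfg A [synth_config()].
#' @return Character vector of OBO lines, with attributes `branch_of` (named
#'   integer: branch index per term, 0 for the root) and `root`.
#' @export
generate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, "ontology"))
  n <- cfg$n_terms
  ids <- synth_term_id(seq_len(n))
  root <- ids[1]
  branch_roots <- 1L + seq_len(cfg$n_branches)
  parent <- integer(n) # tree parent index; 0 for root
  branch_of <- integer(n)
  parent[branch_roots] <- 1L
  branch_of[branch_roots] <- seq_len(cfg$n_branches)
  # a layer of ~5 sub-branch roots per branch, then deep terms grown under
  # them: pathways concentrate on sub-branches, so the layer width controls
  # how many functionally distinct processes a theme offers
  per_branch <- max(1L, min(5L, (n - 1L - cfg$n_branches) %/%
                              (2L * cfg$n_branches)))
  per_branch <- min(per_branch,
                    max(1L, (n - 1L - cfg$n_branches) %/% cfg$n_branches))
  n_sub_layer <- per_branch * cfg$n_branches
  sub_layer <- 1L + cfg$n_branches + seq_len(n_sub_layer)
  for (i in sub_layer) {
    b <- 1L + (i - 2L - cfg$n_branches) %% cfg$n_branches
    parent[i] <- branch_roots[b]
    branch_of[i] <- b
  }
  deep <- setdiff(seq_len(n), c(1L, branch_roots, sub_layer))
  for (i in deep) {
    cand <- sub_layer[sub_layer < i]
    cand <- c(cand, deep[deep < i])
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    parent[i] <- p
    branch_of[i] <- branch_of[p]
  }
  # sub-branch (tree) membership: the child of the branch root each term
  # descends from; NA for the root and branch roots themselves
  subtree_root <- rep(NA_integer_, n)
  subtree_root[sub_layer] <- sub_layer
  for (i in sort(deep)) subtree_root[i] <- subtree_root[parent[i]]
  edges <- tibble::tibble(child = ids[-1], parent = ids[parent[-1]])
  # extra DAG edges: a second parent with smaller index (acyclicity by
  # construction), within the same branch so the branch decomposition that
  # drives annotation propagation stays clean
  extra <- list()
  for (i in setdiff(seq_len(n), c(1L, branch_roots))) {
    if (stats::runif(1) < cfg$dag_extra_edge_prob) {
      cand <- which(branch_of == branch_of[i])
      cand <- setdiff(cand[cand < i], c(i, parent[i]))
      if (length(cand)) {
        p2 <- if (length(cand) == 1L) cand else sample(cand, 1L)
        extra[[length(extra) + 1L]] <- tibble::tibble(child = ids[i],
                                                      parent = ids[p2])
      }
    }
  }
  edges <- dplyr::bind_rows(edges, dplyr::bind_rows(extra))
  edges$relation <- ifelse(stats::runif(nrow(edges)) < cfg$part_of_fraction,
                           "part_of", "is_a")
  lines <- c("format-version: 1.2", "ontology: synthetic-bp", "")
  for (i in seq_len(n)) {
    stanza <- c("[Term]",
                paste0("id: ", ids[i]),
                paste0("name: synthetic process ", i),
                "namespace: biological_process")
    rows <- which(edges$child == ids[i])
    for (r in rows) {
      stanza <- c(stanza, if (edges$relation[r] == "is_a") {
        paste0("is_a: ", edges$parent[r])
      } else {
        paste0("relationship: part_of ", edges$parent[r])
      })
    }
    lines <- c(lines, stanza, "")
  }
  structure(lines,
            branch_of = stats::setNames(branch_of, ids),
            subtree_of = stats::setNames(
              ifelse(is.na(subtree_root), NA_character_, ids[subtree_root]),
              ids),
            root = root,
            edges = edges,
            ancestors = compute_ancestors(ids, edges))
}

#' Generate synthetic GAF annotations
#'
#' Each gene is assigned a home term (a specific process, biased toward the
#' deep end of one ontology branch) and receives a Poisson-distributed number
#' (>= 1) of direct annotations: its home term and the home term's ancestor
#' path, topped up with uniform noise terms from anywhere in the ontology.
#' Genes sharing a home neighbourhood therefore share specific deep terms,
#' which is what makes pathway enrichment profiles specific rather than
#' generic. An `iea_fraction` stratum of genes carries only IEA evidence and
#' is lost to evidence filtering.
#'
#' @param cfg A [synth_config()].
#' @param ontology Output of [generate_ontology()] (carries the branch and
#'   ancestor structure as attributes).
#' @return Character vector of GAF 2.2 lines with attributes `gene_branch`
#'   (named integer home branch per gene), `gene_home` (named character:
#'   each gene's home term), `iea_only` (the IEA-only genes) and
#'   `ontology_info` (branch/ancestor structure passed through to
#'   [generate_pathways()]).
#' @export
generate_annotations <- function(cfg, ontology) {
  stopifnot(inherits(cfg, "synth_config"))
  branch_of <- attr(ontology, "branch_of")
  anc <- attr(ontology, "ancestors")
  if (is.null(branch_of) || is.null(anc)) {
    rlang::abort("ontology lacks branch structure")
  }
  set.seed(derive_seed(cfg$seed, "annotations"))
  ids <- names(branch_of)
  root <- ids[branch_of == 0L]
  non_root <- ids[branch_of > 0L]
  depth <- lengths(anc) # >= tree depth; 0 for the root
  genes <- synth_gene_id(seq_len(cfg$n_genes))
  gene_branch <- sample(seq_len(cfg$n_branches), cfg$n_genes, replace = TRUE)
  names(gene_branch) <- genes
  subtree_of <- attr(ontology, "subtree_of")
  branch_counter <- integer(cfg$n_branches)
  gene_home <- vapply(genes, function(g) {
    b <- gene_branch[[g]]
    subs <- sort(unique(stats::na.omit(subtree_of[branch_of == b])))
    branch_counter[b] <<- branch_counter[b] + 1L
    # cycle genes through the branch's sub-branches so every specific
    # process has a comparable gene pool
    s <- subs[1L + (branch_counter[b] - 1L) %% length(subs)]
    if (s == subs[1L]) {
      # the branch's first sub-branch is its signature process: annotated
      # coherently at the sub-branch term itself
      s
    } else {
      home <- non_root[!is.na(subtree_of[non_root]) &
                         subtree_of[non_root] == s]
      if (length(home) == 1L) home else
        sample(home, 1L, prob = depth[home]) # deeper terms more likely
    }
  }, character(1))
  iea_only <- sort(sample(genes, round(cfg$iea_fraction * cfg$n_genes)))
  rows <- list()
  for (g in genes) {
    k <- max(1L, stats::rpois(1, cfg$terms_per_gene))
    path <- c(gene_home[[g]], setdiff(anc[[gene_home[[g]]]], root))
    branch_terms <- non_root[branch_of[non_root] == gene_branch[[g]]]
    # home_branch_bias of the terms stay in the gene's branch: the home
    # term's ancestor path first, then other branch terms; the rest is
    # ontology-wide noise
    n_branch <- max(1L, round(cfg$home_branch_bias * k))
    n_home <- min(length(path), n_branch)
    local_pool <- setdiff(branch_terms, path)
    n_local <- min(max(0L, n_branch - n_home), length(local_pool))
    global_pool <- setdiff(non_root, c(path, local_pool))
    n_global <- min(max(0L, k - n_home - n_local), length(global_pool))
    pick <- c(path[seq_len(n_home)],
              if (n_local > 0) sample(local_pool, n_local) else character(0),
              if (n_global > 0) sample(global_pool, n_global) else character(0))
    ev <- if (g %in% iea_only) "IEA" else "EXP"
    rows[[g]] <- paste("SYNDB", g, g, "", pick, "SYN:0001", ev, "",
                       "P", "", "", "protein", "taxon:9606", "20260101",
                       "SYNDB", sep = "\t")
  }
  lines <- c("!gaf-version: 2.2", unlist(rows, use.names = FALSE))
  structure(lines, gene_branch = gene_branch, gene_home = gene_home,
            iea_only = iea_only,
            ontology_info = list(branch_of = branch_of, ancestors = anc,
                                 subtree_of = subtree_of,
                                 edges = attr(ontology, "edges"),
                                 root = root))
}

#' Generate synthetic GMT pathways with ground truth
#'
#' Pathways are organized into themes mapped onto ontology branches: most of
#' a pathway's genes come from genes whose home branch is the theme's branch,
#' a core subset shared across the theme inflates gene memberships, and the
#' remainder is background noise. Exact duplicates, disease/drug/addiction
#' -named decoys and sub-enrichment-size pathways are planted so every
#' curation stage has work to do.
#'
#' @param cfg A [synth_config()].
#' @param annotations Output of [generate_annotations()] (for gene home
#'   branches).
#' @return Character vector of GMT lines with attribute `truth`: a tibble
#'   (`id`, `name`, `theme`, `status` in
#'   normal/crosstalk/duplicate/disease_name/tiny, `duplicate_of`).
#' @export
generate_pathways <- function(cfg, annotations) {
  stopifnot(inherits(cfg, "synth_config"))
  gene_branch <- attr(annotations, "gene_branch")
  gene_home <- attr(annotations, "gene_home")
  info <- attr(annotations, "ontology_info")
  if (is.null(gene_branch) || is.null(gene_home) || is.null(info)) {
    rlang::abort("annotations lack generator structure")
  }
  set.seed(derive_seed(cfg$seed, "pathways"))
  genes <- names(gene_branch)
  branch_of <- info$branch_of
  term_subtree <- info$subtree_of
  # a pathway concentrates its genes on one sub-branch so its most
  # significant enriched term is a specific term, not the branch root
  gene_subtree <- term_subtree[gene_home]
  names(gene_subtree) <- genes
  subtree_of <- lapply(seq_len(cfg$n_branches), function(b) {
    subs <- sort(unique(stats::na.omit(term_subtree[branch_of == b])))
    stats::setNames(as.list(subs), subs)
  })
  sub_pool <- lapply(seq_len(cfg$n_branches), function(b) {
    lapply(subtree_of[[b]], function(s) {
      sort(genes[gene_subtree == s])
    })
  })
  theme_pool <- lapply(seq_len(cfg$n_themes),
                       function(b) genes[gene_branch == b])
  recs <- list()
  idx <- 0L
  add <- function(name, gs, theme, status, duplicate_of = NA_character_,
                  subtree = NA_character_) {
    idx <<- idx + 1L
    id <- sprintf("PW%04d", idx)
    recs[[idx]] <<- list(id = id, name = name, genes = gs, theme = theme,
                         status = status, duplicate_of = duplicate_of,
                         subtree = subtree)
    id
  }
  n_bridge <- round(cfg$crosstalk_fraction * cfg$pathways_per_theme)
  # each cross-talk pathway owns a few connector genes found in no other
  # pathway; covering the last fraction of the gene universe then requires
  # keeping the bridges, as it does for real connector proteins
  bridge_partner <- function(th, b) 1L + (th - 1L + b) %% cfg$n_themes
  bridge_connectors <- list()
  if (n_bridge > 0 && cfg$n_themes > 1L) {
    for (th in seq_len(cfg$n_themes)) {
      for (b in seq_len(n_bridge)) {
        pool2 <- setdiff(c(theme_pool[[th]],
                           theme_pool[[bridge_partner(th, b)]]),
                         unlist(bridge_connectors))
        bridge_connectors[[paste(th, b)]] <- sample(pool2, min(4L,
                                                               length(pool2)))
      }
    }
  }
  reserved <- unlist(bridge_connectors, use.names = FALSE)
  theme_pool <- lapply(theme_pool, setdiff, y = reserved)
  sub_pool <- lapply(sub_pool, function(subs) lapply(subs, setdiff,
                                                     y = reserved))
  open_genes <- setdiff(genes, reserved)
  draw_from <- function(pools, n_themed, size) {
    # core first (overlap inflation), then ~70% of the themed quota from the
    # sub-branch pool and the rest branch-wide, so every pathway also carries
    # genes that enrich the branch-level term shared across its theme
    core <- unlist(lapply(pools, function(p) utils::head(p$core, 7L)))
    gs <- character(0)
    n_core <- min(round(cfg$overlap_inflation * size), length(core))
    if (n_core > 0) gs <- core[seq_len(n_core)]
    quota <- ceiling(n_themed / length(pools))
    for (p in pools) {
      n_sub <- ceiling(0.7 * quota)
      avail <- setdiff(p$pool, gs)
      if (length(avail)) gs <- c(gs, sample(avail, min(n_sub, length(avail))))
      avail <- setdiff(p$branch, gs)
      n_br <- max(0L, min(quota - n_sub, length(avail)))
      if (n_br > 0) gs <- c(gs, sample(avail, n_br))
    }
    unique(gs)
  }
  # every theme has a signature sub-branch; its leading genes recur in all
  # the theme's pathways (the shared-core redundancy real collections show),
  # so every pathway profile carries the signature term next to its own
  # sub-branch term and within-theme similarity is uniformly high
  sig_core <- lapply(seq_len(cfg$n_themes), function(th) {
    utils::head(sub_pool[[th]][[1L]], 7L)
  })
  for (th in seq_len(cfg$n_themes)) {
    subs <- names(subtree_of[[th]])
    cyc <- subs
    for (j in seq_len(cfg$pathways_per_theme)) {
      bridge <- j > cfg$pathways_per_theme - n_bridge && cfg$n_themes > 1L
      bi <- j - (cfg$pathways_per_theme - n_bridge) # bridge index, if any
      next_th <- if (bridge) bridge_partner(th, bi) else 1L + th %% cfg$n_themes
      s <- cyc[1L + (j - 1L) %% length(cyc)]
      pools <- list(list(core = sig_core[[th]],
                         pool = sub_pool[[th]][[s]],
                         branch = theme_pool[[th]]))
      if (bridge) {
        # a cross-talk pathway couples the signature processes of two
        # themes: half its genes from each signature pool, so its profile is
        # the two signature terms and it links the two theme clusters as
        # their weakest retained edges
        pools <- list(list(core = sig_core[[th]],
                           pool = sub_pool[[th]][[1L]],
                           branch = sub_pool[[th]][[1L]]),
                      list(core = sig_core[[next_th]],
                           pool = sub_pool[[next_th]][[1L]],
                           branch = sub_pool[[next_th]][[1L]]))
      }
      size <- max(4L, round(stats::rlnorm(1, log(cfg$pathway_size_median),
                                          if (bridge) cfg$pathway_size_sdlog / 3
                                          else cfg$pathway_size_sdlog)))
      size <- min(size, length(genes))
      gs <- draw_from(pools, round(0.85 * size), size)
      if (bridge) {
        # no background filler: a cross-talk pathway is a focused coupling,
        # and its profile should stay the two sub-branch terms
        gs <- unique(c(gs, bridge_connectors[[paste(th, bi)]]))
      } else {
        n_bg <- size - length(gs)
        if (n_bg > 0) gs <- unique(c(gs, sample(setdiff(open_genes, gs),
                                                n_bg)))
      }
      add(sprintf("theme %d process pathway %d", th, j), sort(gs), th,
          if (bridge) "crosstalk" else "normal",
          subtree = if (bridge) NA_character_ else s)
    }
  }
  # exact duplicates of randomly chosen pathways
  n_dup <- round(cfg$duplicate_fraction * length(recs))
  if (n_dup > 0) {
    src <- sample(seq_along(recs), n_dup)
    for (s in src) {
      r <- recs[[s]]
      add(paste0(r$name, " (alternate source)"), r$genes, r$theme,
          "duplicate", duplicate_of = r$id, subtree = r$subtree)
    }
  }
  # disease / drug / addiction named decoys, random gene content
  decoys <- c("synthetic carcinoma pathway", "chronic viral infection",
              "doxorubicin metabolism pathway", "statin pharmacokinetics",
              "cocaine addiction response", "nicotine dependence signalling")
  for (nm in utils::head(decoys, cfg$n_disease_named)) {
    gs <- sort(sample(open_genes, cfg$pathway_size_median))
    add(nm, gs, NA_integer_, "disease_name")
  }
  # pathways below the enrichment size floor
  for (j in seq_len(cfg$n_tiny)) {
    gs <- sort(sample(open_genes, 3L))
    add(sprintf("tiny process pathway %d", j), gs, NA_integer_, "tiny")
  }
  lines <- vapply(recs, function(r) {
    paste(c(r$id, r$name, r$genes), collapse = "\t")
  }, character(1))
  truth <- tibble::tibble(
    id = vapply(recs, `[[`, character(1), "id"),
    name = vapply(recs, `[[`, character(1), "name"),
    theme = vapply(recs, function(r) as.integer(r$theme), integer(1)),
    status = vapply(recs, `[[`, character(1), "status"),
    duplicate_of = vapply(recs, `[[`, character(1), "duplicate_of"),
    subtree = vapply(recs, `[[`, character(1), "subtree"))
  structure(lines, truth = truth)
}

#' Generate synthetic disease annotations with ground truth
#'
#' Planted diseases draw their genes from 3-6 pathways of a single theme, so
#' their enriched pathway nodes are functionally close in the network; null
#' diseases draw genes uniformly from the pathway gene universe. Planted
#' disease names include cancer-system terms so name-based system selection
#' can be exercised.
#'
#' @param cfg A [synth_config()].
#' @param pathways Output of [generate_pathways()].
#' @return Character vector of disease TSV lines (disease id, name, gene,
#'   kind) with attribute `truth`: tibble (`disease_id`, `name`, `type`,
#'   `theme`, `source_pathways` list-column).
#' @export
generate_diseases <- function(cfg, pathways) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- attr(pathways, "truth")
  if (is.null(truth)) rlang::abort("pathways lack ground truth")
  set.seed(derive_seed(cfg$seed, "diseases"))
  ps <- read_gmt(as.character(pathways), source = "synthetic")
  universe <- gene_universe(ps)
  cancer_words <- c("sarcoma", "carcinoma", "melanoma", "leukemia")
  rows <- list()
  t_rows <- list()
  normal <- truth$id[truth$status == "normal"]
  for (d in seq_len(cfg$n_planted_diseases)) {
    th <- 1L + (d - 1L) %% cfg$n_themes
    normal_rows <- truth[truth$status == "normal" & !is.na(truth$theme) &
                           truth$theme == th, ]
    k <- sample(4:6, 1L)
    # one source pathway per sub-branch: the disease perturbs several
    # distinct but functionally adjacent processes of its theme
    subs_avail <- unique(normal_rows$subtree)
    chosen_subs <- sample(subs_avail, min(k, length(subs_avail)))
    src <- vapply(chosen_subs, function(s) {
      cand <- normal_rows$id[normal_rows$subtree == s]
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, character(1))
    if (length(src) < k) {
      extra <- setdiff(normal_rows$id, src)
      src <- c(src, sample(extra, min(k - length(src), length(extra))))
    }
    # draw evenly from every source pathway so each one shows a strong,
    # enrichable overlap with the disease gene set
    per_src <- ceiling(cfg$genes_per_disease / length(src))
    gs <- unlist(lapply(src, function(pid) {
      g <- ps$genes[[match(pid, ps$id)]]
      sample(g, min(per_src, length(g)))
    }), use.names = FALSE)
    gs <- sort(unique(gs))
    id <- sprintf("DIS:P%03d", d)
    nm <- sprintf("synthetic %s %d",
                  cancer_words[1L + (d - 1L) %% length(cancer_words)], d)
    rows[[id]] <- paste(id, nm, gs, "disease", sep = "\t")
    t_rows[[id]] <- tibble::tibble(disease_id = id, name = nm,
                                   type = "planted", theme = th,
                                   source_pathways = list(sort(src)))
  }
  for (d in seq_len(cfg$n_null_diseases)) {
    gs <- sort(sample(universe, cfg$genes_per_disease))
    id <- sprintf("DIS:N%03d", d)
    nm <- sprintf("random disorder %d", d)
    rows[[id]] <- paste(id, nm, gs, "disease", sep = "\t")
    t_rows[[id]] <- tibble::tibble(disease_id = id, name = nm,
                                   type = "null", theme = NA_integer_,
                                   source_pathways = list(character(0)))
  }
  structure(unlist(rows, use.names = FALSE),
            truth = dplyr::bind_rows(t_rows))
}

#' Generate the full synthetic study
#'
#' Runs all four generators under one master seed and returns the texts plus
#' ground truth; optionally writes the files (OBO, GAF, GMT, disease TSV and
#' ground-truth TSVs) to a directory.
#'
#' @param cfg A [synth_config()]; the default is the standard fixture
#'   `std-v1` (seed 17).
#' @param dir Optional output directory.
#' @return List of class `synth_study` with elements `obo`, `gaf`, `gmt`,
#'   `diseases` (character vectors), `pathway_truth`, `disease_truth`
#'   (tibbles) and `config`.
#' @export
generate_study <- function(cfg = synth_config(), dir = NULL) {
  obo <- generate_ontology(cfg)
  gaf <- generate_annotations(cfg, obo)
  gmt <- generate_pathways(cfg, gaf)
  dis <- generate_diseases(cfg, gmt)
  out <- structure(
    list(obo = as.character(obo), gaf = as.character(gaf),
         gmt = as.character(gmt), diseases = as.character(dis),
         pathway_truth = attr(gmt, "truth"),
         disease_truth = attr(dis, "truth"),
         gene_branch = attr(gaf, "gene_branch"),
         config = cfg),
    class = "synth_study")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(out$obo, file.path(dir, "ontology.obo"))
    writeLines(out$gaf, file.path(dir, "annotations.gaf"))
    writeLines(out$gmt, file.path(dir, "pathways.gmt"))
    writeLines(out$diseases, file.path(dir, "diseases.tsv"))
    utils::write.table(out$pathway_truth,
                       file.path(dir, "pathway_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dt <- out$disease_truth
    dt$source_pathways <- vapply(dt$source_pathways, paste,
                                 character(1), collapse = ",")
    utils::write.table(dt, file.path(dir, "disease_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
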