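# Seeded generators for the three synthetic benchmark inputs: compound
# libraries with a controllable grade mix, toy protein-ligand complexes
# with planted contacts of each interaction kind, and scale-free
# PPI-like networks with an optional planted hub. Every generator is a
# pure function of its arguments (seed included): identical calls give
# byte-identical output. Randomness uses R's default Mersenne-Twister
# stream, seeded locally and restored on exit.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.panelEnv <- new.env(parent = emptyenv())

#' The embedded compound panel, scored and stratified by grade
#'
#' Reads the packaged SMILES panel, scores every structure with the
#' default seven-criterion scorer and returns the panel with its grade
#' stratum attached. Cached after the first call.
#'
#' @return data.frame with columns \code{name}, \code{smiles},
#'   \code{s_total}, \code{grade}.
#' @export
compoundPanel <- function() {
  if (!is.null(.panelEnv$panel)) return(.panelEnv$panel)
  path <- system.file("extdata", "compound_panel.tsv",
                      package = "GradeScreen", mustWork = TRUE)
  ln <- readLines(path)
  ln <- ln[!grepl("^[[:space:]]*#", ln) & nzchar(trimws(ln))]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  panel <- data.frame(name = vapply(parts, `[`, "", 1L),
                      smiles = vapply(parts, `[`, "", 2L))
  sc <- cards(scoreCompounds(
    data.frame(identifier = panel$name, smiles = panel$smiles)))
  panel$s_total <- sc$s_total[match(panel$name, sc$identifier)]
  panel$grade <- sc$grade[match(panel$name, sc$identifier)]
  .panelEnv$panel <- panel
  panel
}

# Largest-remainder apportionment of n among the mix proportions.
.apportion <- function(n, mix) {
  exact <- n * mix
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Generate a seeded synthetic compound library with a target grade mix
#'
#' Samples (with replacement) from the embedded panel stratified by
#' grade under the default scorer, apportioning the library size across
#' grades by largest remainder, so the scored grade distribution of the
#' generated library reproduces the target mix up to apportionment.
#' The default mix emulates a screening library dominated by good but
#' not excellent compounds (A 25/171, B 92/171, C 37/171, D 10/171,
#' F 7/171).
#'
#' @param n library size (default 171).
#' @param mix named proportions per grade, summing to 1.
#' @param seed integer seed.
#' @return data.frame of compound records (\code{identifier},
#'   \code{name}, \code{smiles}, \code{source}) in randomized order.
#' @examples
#' lib <- generateCompoundLibrary(20, seed = 7)
#' @export
generateCompoundLibrary <- function(n = 171,
                                    mix = c(A = 25, B = 92, C = 37,
                                            D = 10, F = 7) / 171,
                                    seed = 1) {
  stopifnot(n >= 1)
  if (is.null(names(mix)) || !all(names(mix) %in% c("A", "B", "C", "D", "F")))
    stop("mix must be named over grades A-F")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    stop("mix proportions must be non-negative and sum to 1")
  panel <- compoundPanel()
  counts <- .apportion(n, mix)
  .withSeed(seed, {
    rows <- integer()
    for (g in names(counts)) {
      if (counts[[g]] == 0L) next
      stratum <- which(panel$grade == g)
      if (!length(stratum))
        stop("unachievable mix: no panel compound of grade ", g)
      rows <- c(rows, stratum[sample.int(length(stratum), counts[[g]],
                                         replace = TRUE)])
    }
    rows <- rows[sample.int(length(rows))]   # shuffle grade blocks together
    data.frame(identifier = paste0(panel$name[rows], "_", seq_along(rows)),
               name = panel$name[rows],
               smiles = panel$smiles[rows],
               source = "synthetic")
  })
}

# --- toy protein-ligand complexes -----------------------------------

.pdbLine <- function(record, serial, name, resid, chain, resno,
                     x, y, z, element) {
  if (nchar(name) <= 3L) name <- paste0(" ", name)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, "", resid, chain, resno, "",
          x, y, z, 1, 20, element)
}

#' Generate a toy protein-ligand complex with planted contacts
#'
#' Builds a pseudo-complex in which exactly the requested contacts
#' satisfy the interaction cutoffs: each planted contact lives in its
#' own spatial motif (motif centers 16 A apart) with the contact
#' distance sampled at least 0.1 A inside its cutoff, while every
#' non-planted ligand/protein pair is kept at least 0.5 A outside every
#' cutoff. Motifs: hydroxyl-O to Ser OG (hydrogen bond), carboxylate-O
#' to Lys NZ (salt bridge), lone carbon to Leu CD1 (hydrophobic), and
#' benzene ring to Phe ring, coaxial (pi). Filler Ala CB atoms and a
#' few waters sit on a distant shell.
#'
#' @param n_hbond,n_saltbridge,n_hydrophobic,n_pi planted contact
#'   counts per kind.
#' @param n_filler distant pocket filler atoms.
#' @param seed integer seed.
#' @return list with \code{pdb} (PDB text), \code{contacts} (ground
#'   truth data.frame: \code{kind}, \code{ligand_atom}, \code{residue},
#'   \code{distance}) and \code{ligand} (residue name, "LIG").
#' @examples
#' cx <- generateToyComplex(n_hbond = 2, n_hydrophobic = 1, seed = 3)
#' @export
generateToyComplex <- function(n_hbond = 2, n_saltbridge = 1,
                               n_hydrophobic = 2, n_pi = 1,
                               n_filler = 20, seed = 1) {
  stopifnot(n_hbond >= 0, n_saltbridge >= 0, n_hydrophobic >= 0,
            n_pi >= 0, n_filler >= 0)
  kinds <- c(rep("hydrogen-bond", n_hbond),
             rep("salt-bridge", n_saltbridge),
             rep("hydrophobic", n_hydrophobic),
             rep("pi", n_pi))
  .withSeed(seed, {
    lig <- list(); prot <- list(); truth <- list()
    lig_i <- 0L
    addLig <- function(name, el, p) {
      lig_i <<- lig_i + 1L
      lig[[lig_i]] <<- list(name = name, el = el, p = p)
      lig_i
    }
    spacing <- 16
    for (m in seq_along(kinds)) {
      p <- c(m %% 3, (m %/% 3) %% 3, m %/% 9) * spacing
      resno <- 10L * m
      kind <- kinds[m]
      if (kind == "hydrogen-bond") {
        d <- stats::runif(1, 2.7, 3.4)
        addLig(paste0("C", lig_i + 1L), "C", p)
        oi <- addLig(paste0("O", lig_i + 1L), "O", p + c(1.4, 0, 0))
        prot[[length(prot) + 1L]] <- list(name = "OG", el = "O",
          resid = "SER", resno = resno, p = p + c(1.4 + d, 0, 0))
        truth[[length(truth) + 1L]] <- data.frame(kind = kind,
          ligand_atom = oi, residue = paste0("SER", resno, ":A"),
          distance = d)
      } else if (kind == "salt-bridge") {
        d <- stats::runif(1, 4.5, 5.4)
        addLig(paste0("C", lig_i + 1L), "C", p)
        oi <- addLig(paste0("O", lig_i + 1L), "O", p + c(1.25, 0, 0))
        addLig(paste0("O", lig_i + 1L), "O",
               p + 1.25 * c(-0.5, 0.866, 0))
        prot[[length(prot) + 1L]] <- list(name = "NZ", el = "N",
          resid = "LYS", resno = resno, p = p + c(1.25 + d, 0, 0))
        truth[[length(truth) + 1L]] <- data.frame(kind = kind,
          ligand_atom = oi, residue = paste0("LYS", resno, ":A"),
          distance = d)
      } else if (kind == "hydrophobic") {
        d <- stats::runif(1, 3.2, 3.9)
        ci <- addLig(paste0("C", lig_i + 1L), "C", p)
        prot[[length(prot) + 1L]] <- list(name = "CD1", el = "C",
          resid = "LEU", resno = resno, p = p + c(d, 0, 0))
        truth[[length(truth) + 1L]] <- data.frame(kind = kind,
          ligand_atom = ci, residue = paste0("LEU", resno, ":A"),
          distance = d)
      } else {
        d <- stats::runif(1, 4.6, 5.4)
        first <- NA_integer_
        ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
        for (k in 0:5) {
          th <- k * pi / 3
          ii <- addLig(paste0("C", lig_i + 1L), "C",
                       p + 1.39 * c(cos(th), sin(th), 0))
          if (k == 0L) first <- ii
          prot[[length(prot) + 1L]] <- list(name = ring_names[k + 1L],
            el = "C", resid = "PHE", resno = resno,
            p = p + c(0, 0, d) + 1.39 * c(cos(th), sin(th), 0))
        }
        truth[[length(truth) + 1L]] <- data.frame(kind = "pi",
          ligand_atom = first, residue = paste0("PHE", resno, ":A"),
          distance = d)
      }
    }
    if (lig_i == 0L)  # zero planted contacts still needs a ligand
      addLig("C1", "C", c(0, 0, 0))
    # bounding box of everything placed so far, for the filler shell
    all_p <- do.call(rbind, c(lapply(lig, `[[`, "p"),
                              lapply(prot, `[[`, "p"),
                              list(c(0, 0, 0))))
    ctr <- (apply(all_p, 2, max) + apply(all_p, 2, min)) / 2
    radius <- sqrt(max(rowSums(sweep(all_p, 2, ctr)^2))) + 12
    shell <- function() {
      v <- stats::rnorm(3)
      ctr + radius * v / sqrt(sum(v^2))
    }
    for (i in seq_len(n_filler))
      prot[[length(prot) + 1L]] <- list(name = "CB", el = "C",
        resid = "ALA", resno = 500L + i, p = shell())
    waters <- lapply(1:3, function(i)
      list(name = "O", el = "O", resno = 800L + i, p = shell()))
    lines <- character(); serial <- 0L
    for (a in lig) {
      serial <- serial + 1L
      lines <- c(lines, .pdbLine("HETATM", serial, a$name, "LIG", "L",
                                 900L, a$p[1], a$p[2], a$p[3], a$el))
    }
    for (a in prot) {
      serial <- serial + 1L
      lines <- c(lines, .pdbLine("ATOM", serial, a$name, a$resid, "A",
                                 a$resno, a$p[1], a$p[2], a$p[3], a$el))
    }
    for (a in waters) {
      serial <- serial + 1L
      lines <- c(lines, .pdbLine("HETATM", serial, a$name, "HOH", "W",
                                 a$resno, a$p[1], a$p[2], a$p[3], a$el))
    }
    lines <- c(lines, "END")
    truth_tab <- if (length(truth)) do.call(rbind, truth) else
      data.frame(kind = character(), ligand_atom = integer(),
                 residue = character(), distance = numeric())
    truth_tab <- truth_tab[order(truth_tab$kind, truth_tab$ligand_atom,
                                 truth_tab$residue), , drop = FALSE]
    rownames(truth_tab) <- NULL
    list(pdb = paste(lines, collapse = "\n"), contacts = truth_tab,
         ligand = "LIG")
  })
}

# --- PPI-like networks ----------------------------------------------

#' Generate a scale-free PPI-like edge list with an optional planted hub
#'
#' Preferential-attachment topology over \code{n} genes; edge
#' confidence scores are drawn from a two-component mixture so that a
#' configurable fraction falls below the conventional 400 threshold
#' (below: uniform 150-399, above: uniform 400-1000). When a hub is
#' planted, an extra gene \code{"HUB0"} is wired to a fraction of the
#' other genes, with scores from the same mixture.
#'
#' @param n number of background genes (default 311).
#' @param m preferential-attachment edges per new node.
#' @param hub plant a hub gene?
#' @param hub_fraction fraction of genes wired to the hub.
#' @param below_fraction expected fraction of edges scoring below 400.
#' @param seed integer seed.
#' @return list with \code{edges} (data.frame \code{geneA},
#'   \code{geneB}, \code{combined_score}) and \code{hub} (planted hub
#'   symbol or \code{NA}).
#' @examples
#' net <- generatePPINetwork(n = 50, seed = 11)
#' @export
generatePPINetwork <- function(n = 311, m = 2, hub = TRUE,
                               hub_fraction = 0.3, below_fraction = 0.4,
                               seed = 1) {
  stopifnot(n >= 2, m >= 1, hub_fraction >= 0, hub_fraction <= 1,
            below_fraction >= 0, below_fraction <= 1)
  .withSeed(seed, {
    g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    gene <- sprintf("G%03d", seq_len(n))
    edges <- data.frame(geneA = gene[el[, 1]], geneB = gene[el[, 2]])
    hub_name <- NA_character_
    if (hub) {
      hub_name <- "HUB0"
      partners <- sample(gene, max(1L, round(hub_fraction * n)))
      edges <- rbind(edges, data.frame(geneA = hub_name,
                                       geneB = partners))
    }
    draw_low <- stats::runif(nrow(edges)) < below_fraction
    score <- integer(nrow(edges))
    score[draw_low] <- sample(150:399, sum(draw_low), replace = TRUE)
    score[!draw_low] <- sample(400:1000, sum(!draw_low), replace = TRUE)
    edges$combined_score <- score
    list(edges = edges, hub = hub_name)
  })
}

#' Write an edge list as a STRING-style TSV
#'
#' @param edges data.frame with columns \code{geneA}, \code{geneB},
#'   \code{combined_score} (e.g. from [generatePPINetwork()]).
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
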