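# Whole-network orchestration: per-gene decoupled inference, structure
# scoring against a reference network, and file I/O.

# Deterministic sub-problem seed derived from the master seed and the gene
# name, so per-gene runs are independent and column order does not matter.
derive_seed <- function(master_seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 10000L
  (as.integer(master_seed) * 10007L + h * 131L) %% 2147483629L + 1L
}

#' Infer a full network from a time-series profile
#'
#' Runs [run_pio()] independently on every gene's decoupled sub-problem
#' (seeds derived from `cfg$seed` and the gene names) and assembles the
#' per-gene global bests into an `ssystem` network. A failed sub-problem is
#' reported for its gene without aborting the others.
#'
#' @param profile An [expression_profile()].
#' @param cfg A [pio_config()]; `cfg$fit_cfg` selects the objective.
#' @param prior Optional [prior_structure()] for the combined objective.
#' @param final_sensitivity Attach a final m-MPSA report per gene.
#' @param control A [sim_control()] list.
#' @param verbose Print per-gene progress to stderr.
#' @return A list of class `inference_result`: `network`,
#'   `per_gene_fitness`, `per_gene_mean_sensitivity`, `per_gene_seed`,
#'   `histories`, `errors`, `cfg`.
#' @export
infer_network <- function(profile, cfg = pio_config(), prior = NULL,
                          final_sensitivity = FALSE,
                          control = sim_control(), verbose = FALSE) {
  stopifnot(inherits(profile, "expression_profile"))
  if (anyDuplicated(profile$names))
    stop("gene names must be unique")
  # canonicalize the gene order so results are equivariant under column
  # permutation of the input (per-gene seeds are tied to names, and the RNG
  # stream inside a sub-problem must see the same parameter layout)
  ord <- order(profile$names)
  if (!identical(ord, seq_along(ord))) {
    canon <- expression_profile(profile$values[, ord, drop = FALSE],
                                profile$times, profile$names[ord])
    if (!is.null(prior))
      prior <- prior_structure(prior$g_known[ord, ord, drop = FALSE],
                               prior$h_known[ord, ord, drop = FALSE])
    res <- infer_network(canon, cfg, prior, final_sensitivity, control,
                         verbose)
    back <- order(ord)
    net <- res$network
    genes <- lapply(seq_along(back), function(i) {
      gp <- network_gene(net, back[i])
      gene_parameters(gp$alpha, gp$beta, gp$g[back], gp$h[back], i,
                      check_ranges = FALSE)
    })
    res$network <- s_system(genes, profile$names)
    res$per_gene_fitness <- res$per_gene_fitness[profile$names]
    res$per_gene_mean_sensitivity <-
      res$per_gene_mean_sensitivity[profile$names]
    res$per_gene_seed <- res$per_gene_seed[profile$names]
    res$histories <- res$histories[back]
    return(res)
  }
  N <- ncol(profile$values)
  genes <- vector("list", N)
  fit <- rep(NA_real_, N)
  sens <- rep(NA_real_, N)
  seeds <- integer(N)
  histories <- vector("list", N)
  errors <- setNames(vector("list", N), profile$names)
  for (i in seq_len(N)) {
    seeds[i] <- derive_seed(cfg$seed, profile$names[i])
    sub_cfg <- cfg
    sub_cfg$seed <- seeds[i]
    if (verbose)
      message("gene ", profile$names[i], " (", i, "/", N, "), seed ",
              seeds[i])
    res <- tryCatch(
      run_pio(decoupled_problem(profile, i, cfg$fit_cfg, prior, control),
              sub_cfg, final_sensitivity = final_sensitivity),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[i]] <- conditionMessage(res)
      genes[[i]] <- gene_parameters(0, 0, numeric(N), numeric(N), i)
      next
    }
    genes[[i]] <- res$params
    fit[i] <- res$fitness
    histories[[i]] <- res$history
    if (!is.null(res$final_report))
      sens[i] <- mean_sensitivity(res$final_report)
  }
  structure(list(network = s_system(genes, profile$names),
                 per_gene_fitness = setNames(fit, profile$names),
                 per_gene_mean_sensitivity = setNames(sens, profile$names),
                 per_gene_seed = setNames(seeds, profile$names),
                 histories = histories,
                 errors = Filter(Negate(is.null), errors),
                 cfg = cfg),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("Inferred S-system network (", length(x$network$names), "genes )\n")
  cat("per-gene fitness:\n")
  print(signif(x$per_gene_fitness, 4))
  if (any(!is.na(x$per_gene_mean_sensitivity))) {
    cat("per-gene mean sensitivity:\n")
    print(signif(x$per_gene_mean_sensitivity, 4))
  }
  if (length(x$errors))
    cat("failed genes:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Zero/non-zero structure accuracy of an inferred network
#'
#' Percentage of the `2 N^2` kinetic-order slots (all `g_ij` and `h_ij`)
#' whose zero/non-zero status (magnitude below `zero_threshold` counts as
#' zero) matches the reference network.
#'
#' @param inferred,truth `ssystem` networks of equal dimension.
#' @param zero_threshold Zero cutoff applied to both networks.
#' @return Percentage in \[0, 100\].
#' @export
structure_accuracy <- function(inferred, truth, zero_threshold = 0.1) {
  if (n_genes(inferred) != n_genes(truth))
    stop("networks differ in dimension")
  zi <- abs(cbind(inferred$G, inferred$H)) < zero_threshold
  zt <- abs(cbind(truth$G, truth$H)) < zero_threshold
  100 * mean(zi == zt)
}

# ---- file I/O -------------------------------------------------------------

#' Read an expression profile from delimited text
#'
#' Expects a header row, a first column named `time` and one numeric column
#' per gene. Comma- and tab-separated files are both accepted (by
#' extension: `.tsv`/`.tab` use tabs).
#'
#' @param path File path.
#' @return An [expression_profile()].
#' @export
load_profile <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (ncol(df) < 2) stop("profile must have a time column and >= 1 gene")
  if (tolower(names(df)[1]) != "time")
    stop("first column must be named 'time', found '", names(df)[1], "'")
  bad <- which(is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("missing/non-numeric cell at row ", bad[1, 1], ", column '",
         names(df)[bad[1, 2]], "'")
  expression_profile(as.matrix(df[, -1, drop = FALSE]), df[[1]],
                     names(df)[-1])
}

#' Write an expression profile as delimited text
#'
#' @param profile An [expression_profile()].
#' @param path Output path; `.tsv`/`.tab` write tabs, otherwise commas.
#' @return `path`, invisibly.
#' @export
save_profile <- function(profile, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(time = profile$times, profile$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a network as JSON
#'
#' Document layout: `{names, genes: [{alpha, beta, g, h}, ...]}`; the
#' round-trip through [load_network()] reproduces the parameters exactly.
#'
#' @param net An `ssystem` network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  doc <- list(names = net$names,
              genes = lapply(seq_along(net$names), function(i)
                list(alpha = net$alpha[i], beta = net$beta[i],
                     g = net$G[i, ], h = net$H[i, ])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path Path to a file written by [save_network()].
#' @return An `ssystem` network.
#' @export
load_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- lapply(seq_along(doc$names), function(i)
    gene_parameters(doc$genes$alpha[i], doc$genes$beta[i],
                    unlist(doc$genes$g[i]), unlist(doc$genes$h[i]), i,
                    check_ranges = FALSE))
  s_system(genes, doc$names)
}

#' Write / read a network as flat CSV
#'
#' One row per gene: `gene, alpha, beta, g1..gN, h1..hN`.
#'
#' @param net An `ssystem` network.
#' @param path File path.
#' @return `path` (writer) or an `ssystem` (reader).
#' @export
save_network_csv <- function(net, path) {
  N <- length(net$names)
  df <- data.frame(gene = net$names, alpha = net$alpha, beta = net$beta,
                   net$G, net$H, check.names = FALSE)
  names(df)[-(1:3)] <- c(paste0("g", seq_len(N)), paste0("h", seq_len(N)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_network_csv
#' @export
load_network_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  N <- (ncol(df) - 3) / 2
  genes <- lapply(seq_len(nrow(df)), function(i)
    gene_parameters(df$alpha[i], df$beta[i],
                    as.numeric(df[i, 3 + seq_len(N)]),
                    as.numeric(df[i, 3 + N + seq_len(N)]), i,
                    check_ranges = FALSE))
  s_system(genes, as.character(df$gene))
}

#' Network edge list (SIF-style)
#'
#' One row per kinetic order of magnitude at least `zero_threshold`:
#' `source`, `interaction` (`synthesis+`, `synthesis-`, `degradation+`,
#' `degradation-` by process and sign), `target`.
#'
#' @param net An `ssystem` network.
#' @param zero_threshold Magnitude cutoff for an edge.
#' @return A data frame with columns `source`, `interaction`, `target`.
#' @export
network_edges <- function(net, zero_threshold = 0.1) {
  edges <- function(M, process) {
    idx <- which(abs(M) >= zero_threshold, arr.ind = TRUE)
    if (nrow(idx) == 0)
      return(data.frame(source = character(), interaction = character(),
                        target = character()))
    data.frame(source = net$names[idx[, 2]],
               interaction = paste0(process,
                                    ifelse(M[idx] > 0, "+", "-")),
               target = net$names[idx[, 1]])
  }
  rbind(edges(net$G, "synthesis"), edges(net$H, "degradation"))
}

#' Write an inference report as JSON
#'
#' Captures the run configuration, per-gene seeds, fitness and mean
#' sensitivity, the inferred parameters and the thresholded edge list.
#'
#' @param result An `inference_result` from [infer_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_report <- function(result, path) {
  net <- result$network
  cfg <- result$cfg
  doc <- list(
    config = cfg[!vapply(cfg, is.list, TRUE)],
    per_gene = list(names = net$names,
                    seed = result$per_gene_seed,
                    fitness = result$per_gene_fitness,
                    mean_sensitivity = result$per_gene_mean_sensitivity),
    network = list(names = net$names, alpha = net$alpha, beta = net$beta,
                   G = net$G, H = net$H),
    edges = network_edges(net, cfg$fit_cfg$zero_threshold),
    errors = result$errors)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
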