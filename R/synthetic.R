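#' Toy transmembrane topology grammar
#'
#' A fully specified 3-label CHMM over \{i, M, o\} used as the package's
#' test-bed and documentation model: one inside-loop state `i`, one
#' outside-loop state `o`, and a chain of five membrane states `M1..M5`
#' whose chaining enforces a minimum TM segment length of 5 (the last chain
#' state may repeat, so segments are 5 or longer). The five membrane states
#' share one tied emission table. Emission tables are hard-coded:
#' hydrophobic-biased in the membrane, polar-biased inside, and
#' small/turn-residue-biased outside.
#'
#' Transitions: `i -> i` 0.85, `i -> M1` 0.15 (likewise from `o`);
#' `M1..M4` chain deterministically; `M5 -> M5` 0.55, `M5 -> i` 0.225,
#' `M5 -> o` 0.225. Begin: `i` and `o` with probability 0.5 each.
#'
#' @return A [topology_model()] in emission-table mode.
#' @export
#' @examples
#' toy_topology_model()
toy_topology_model <- function() {
  alphabet <- aa_alphabet()
  states <- c("i", "M1", "M2", "M3", "M4", "M5", "o")
  label_map <- c(i = "i", M1 = "M", M2 = "M", M3 = "M", M4 = "M",
                 M5 = "M", o = "o")
  trans <- matrix(0, 7, 7, dimnames = list(states, states))
  trans["i", c("i", "M1")] <- c(0.85, 0.15)
  trans["o", c("o", "M1")] <- c(0.85, 0.15)
  trans["M1", "M2"] <- 1
  trans["M2", "M3"] <- 1
  trans["M3", "M4"] <- 1
  trans["M4", "M5"] <- 1
  trans["M5", c("M5", "i", "o")] <- c(0.55, 0.225, 0.225)
  biased_table <- function(favored, mass) {
    e <- rep((1 - mass) / (20 - length(favored)), 20)
    e[match(favored, alphabet)] <- mass / length(favored)
    e
  }
  emissions <- rbind(
    i = biased_table(c("D", "E", "K", "R", "N", "Q", "S", "T", "H"), 0.63),
    M = biased_table(c("A", "I", "L", "V", "F", "M", "W", "C"), 0.68),
    o = biased_table(c("G", "P", "Y", "S", "T", "N"), 0.48))
  tie <- c(i = "i", M1 = "M", M2 = "M", M3 = "M", M4 = "M", M5 = "M",
           o = "o")
  topology_model(states, label_map, begin = c(i = 0.5, o = 0.5),
                 trans = trans, emissions = emissions, tie = tie,
                 alphabet = alphabet)
}

#' Specification for a synthetic labeled-sequence generator
#'
#' Two generator kinds share the state grammar of a base model:
#' `"chmm"` draws residues from the model's own (tied) emission tables, so a
#' first-order CHMM is the true model; `"context"` draws each residue from a
#' distribution conditioned on the state label *and the previous residue*,
#' a process whose label signal partly lives in neighboring-residue
#' patterns that a windowed emission network can exploit but a first-order
#' CHMM cannot.
#'
#' The default context process: in membrane states the residue repeats the
#' previous one with probability `repeat_prob` (0.5) and otherwise follows a
#' mildly hydrophobic table; in loop states it is drawn uniformly from the
#' 19 residues different from the previous one. First residues follow the
#' per-label base table.
#'
#' @param kind `"chmm"` or `"context"`.
#' @param model base [topology_model()] (defaults to
#'   [toy_topology_model()]).
#' @param n number of sequences.
#' @param length_range integer range for uniform sequence lengths.
#' @param seed generator seed.
#' @param repeat_prob membrane repeat probability (context kind).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(kind = c("chmm", "context"),
                           model = toy_topology_model(), n = 50,
                           length_range = c(60, 120), seed = 1,
                           repeat_prob = 0.5) {
  kind <- match.arg(kind)
  stopifnot(length_range[1] >= 2, length_range[2] >= length_range[1])
  structure(list(kind = kind, model = model, n = as.integer(n),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed), repeat_prob = repeat_prob),
            class = "generator_spec")
}

context_base_table <- function(label, alphabet = aa_alphabet()) {
  if (label == "M") {
    e <- rep(0.4 / 15, length(alphabet))
    e[match(c("A", "I", "L", "V", "F"), alphabet)] <- 0.6 / 5
    e
  } else rep(1 / length(alphabet), length(alphabet))
}

#' Sample labeled sequences from a generator specification
#'
#' Deterministic given the generator's seed.
#'
#' @param spec a [generator_spec()].
#' @return List of labeled [labeled_sequence()] objects.
#' @export
sample_sequences <- function(spec) {
  model <- spec$model
  alphabet <- model$alphabet
  A <- length(alphabet)
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(j) {
      L <- spec$length_range[1] +
        sample.int(spec$length_range[2] - spec$length_range[1] + 1L, 1) - 1L
      # condition the path on ending outside the membrane so chained TM
      # states are never truncated by the sequence end (min length holds)
      for (attempt in seq_len(1000)) {
        path <- integer(L)
        path[1] <- sample.int(length(model$states), 1, prob = model$begin)
        if (L > 1) for (i in 2:L)
          path[i] <- sample.int(length(model$states), 1,
                                prob = model$trans[path[i - 1], ])
        if (model$label_map[[model$states[path[L]]]] != "M" ||
            !"M" %in% model$labels) break
      }
      labels <- unname(model$label_map[model$states[path]])
      res <- integer(L)
      if (spec$kind == "chmm") {
        for (i in seq_len(L)) {
          g <- model$tie[[model$states[path[i]]]]
          res[i] <- sample.int(A, 1, prob = model$emissions[g, ])
        }
      } else {
        for (i in seq_len(L)) {
          base <- context_base_table(labels[i], alphabet)
          if (i == 1) {
            res[i] <- sample.int(A, 1, prob = base)
          } else if (labels[i] == "M") {
            res[i] <- if (stats::runif(1) < spec$repeat_prob) res[i - 1]
                      else sample.int(A, 1, prob = base)
          } else {
            p <- base
            p[res[i - 1]] <- 0
            res[i] <- sample.int(A, 1, prob = p / sum(p))
          }
        }
      }
      labeled_sequence(sprintf("syn%03d", j),
                       alphabet[res], labels, alphabet = alphabet)
    })
  })
}

#' Stationary label distribution of a topology model
#'
#' Closed-form stationary vector of the state transition matrix aggregated
#' by label; used to check long-run label frequencies of sampled data.
#'
#' @param model a [topology_model()].
#' @return Named numeric vector over labels.
#' @export
stationary_label_distribution <- function(model) {
  ev <- eigen(t(model$trans))
  j <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, j]))
  v <- v / sum(v)
  tapply(v, unname(model$label_map[model$states]), sum)
}

#' Write the synthetic fixture suite
#'
#' Writes the small plain-text fixture files used by tests and examples to
#' `outdir`: a FASTA file, a 3-line label file, a per-sequence profile TSV
#' for the first sequence (position-smoothed one-hot frequencies), and the
#' toy grammar file. All content derives deterministically from `seed`.
#'
#' @param outdir writable directory (created if absent).
#' @param seed generator seed.
#' @param n number of sequences (small: `n <= 50`).
#' @param length_range sequence length range (`<= 120`).
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_suite <- function(outdir, seed = 1, n = 20,
                               length_range = c(60, 120)) {
  stopifnot(n <= 50, length_range[2] <= 120)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- generator_spec("chmm", n = n, length_range = length_range,
                         seed = seed)
  seqs <- sample_sequences(spec)
  paths <- c(
    fasta = file.path(outdir, "synthetic.fasta"),
    labels = file.path(outdir, "synthetic.lab"),
    profile = file.path(outdir, paste0(seqs[[1]]$id, ".profile.tsv")),
    grammar = file.path(outdir, "toy_grammar.model"))
  write_fasta(seqs, paths["fasta"])
  write_labels(seqs, paths["labels"])
  s1 <- seqs[[1]]
  A <- length(attr(s1, "alphabet"))
  onehot <- matrix(0, length(s1), A)
  onehot[cbind(seq_along(s1$idx), s1$idx)] <- 1
  prof <- (onehot + 0.5 / A) / (1 + 0.5)   # smoothed, rows sum to 1
  write_profile(prof, paths["profile"], alphabet = attr(s1, "alphabet"))
  write_model(toy_topology_model(), paths["grammar"])
  invisible(paths)
}
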