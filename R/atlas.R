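#' Default functional-network proportions for the packaged atlas
#'
#' Node counts per functional network follow the published 160-ROI
#' functional parcellation commonly used for whole-brain connectome
#' analyses (cerebellum 18, cingulo-opercular 32, default 34,
#' fronto-parietal 21, occipital 22, sensorimotor 33), expressed as
#' fractions of the atlas size.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
default_network_proportions <- function() {
  counts <- c(Cerebellum = 18, `Cingulo-opercular` = 32, Default = 34,
              `Fronto-parietal` = 21, Occipital = 22, Sensorimotor = 33)
  counts / sum(counts)
}

# Named anchor regions that the packaged 160-node fixture must carry so the
# shipped reference classification model can be mapped onto atlas nodes.
atlas_anchor_nodes <- function() {
  data.frame(
    node_id = c(21L, 30L, 42L, 62L, 98L, 117L, 126L, 143L, 150L),
    label = c("Precuneus", "IPS", "dlPFC", "Ant insula",
              "Parietal/precentral", "Post parietal/postcentral",
              "Occipital", "Lat cerebellum", "Med cerebellum"),
    hemisphere = c("R", "L", "R", "L", "L", "L", "R", "L", "L"),
    network = c("Default", "Default", "Fronto-parietal", "Cingulo-opercular",
                "Sensorimotor", "Sensorimotor", "Occipital", "Cerebellum",
                "Cerebellum"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic atlas table
#'
#' Builds a node table (id, label, hemisphere, network membership, MNI-like
#' coordinates) emulating a functional whole-brain parcellation. The packaged
#' default (160 nodes, [default_network_proportions()]) pins nine named anchor
#' regions to fixed node ids so that the shipped reference classifier's nodes
#' exist in the fixture; all other nodes receive generated labels and seeded
#' pseudo-MNI coordinates. Output is deterministic for a fixed seed.
#'
#' @param n_nodes Number of nodes (default 160).
#' @param network_proportions Named fractions per network, summing to 1.
#' @param seed Integer seed for the coordinate/assignment stream.
#' @return A `data.frame` with columns `node_id`, `label`, `hemisphere`
#'   (`"L"`, `"R"` or `"midline"`), `network`, `x`, `y`, `z` (mm).
#' @export
make_atlas_fixture <- function(n_nodes = 160,
                               network_proportions = default_network_proportions(),
                               seed = 1) {
  if (!is_count(n_nodes) || n_nodes < 1)
    stopf("n_nodes must be a positive count")
  if (is.null(names(network_proportions)) || any(!nzchar(names(network_proportions))))
    stopf("network_proportions must be named")
  if (any(network_proportions < 0) ||
      abs(sum(network_proportions) - 1) > 1e-6)
    stopf("network_proportions must be non-negative and sum to 1")
  networks <- names(network_proportions)
  if (n_nodes < length(networks))
    stopf("n_nodes must be at least the number of networks")

  # per-network node counts by largest remainder
  raw <- network_proportions * n_nodes
  counts <- floor(raw)
  short <- n_nodes - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }

  anchors <- atlas_anchor_nodes()
  anchors <- anchors[anchors$node_id <= n_nodes &
                       anchors$network %in% networks, , drop = FALSE]

  tab <- data.frame(node_id = seq_len(n_nodes), label = NA_character_,
                    hemisphere = NA_character_, network = NA_character_,
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    stringsAsFactors = FALSE)
  with_local_seed(seed, {
    if (nrow(anchors)) {
      tab$label[anchors$node_id] <- anchors$label
      tab$hemisphere[anchors$node_id] <- anchors$hemisphere
      tab$network[anchors$node_id] <- anchors$network
      used <- table(factor(anchors$network, levels = networks))
      counts <- pmax(counts - as.numeric(used), 0)
    }
    free <- which(is.na(tab$network))
    pool <- rep(networks, times = counts)
    # counts may undershoot after anchor subtraction; pad with the largest nets
    while (length(pool) < length(free))
      pool <- c(pool, networks[which.max(counts)])
    pool <- pool[seq_along(free)]
    tab$network[free] <- sample(pool)
    tab$x[free] <- round(runif(length(free), -65, 65), 1)
    tab$y[free] <- round(runif(length(free), -100, 70), 1)
    tab$z[free] <- round(runif(length(free), -45, 75), 1)
    tab$hemisphere[free] <- ifelse(tab$x[free] < -5, "L",
                                   ifelse(tab$x[free] > 5, "R", "midline"))
    if (nrow(anchors)) {
      a <- anchors$node_id
      ax <- round(runif(length(a), 10, 60), 1)
      tab$x[a] <- ifelse(tab$hemisphere[a] == "L", -ax, ax)
      tab$y[a] <- round(runif(length(a), -90, 60), 1)
      tab$z[a] <- round(runif(length(a), -40, 70), 1)
    }
    idx <- which(is.na(tab$label))
    tab$label[idx] <- sprintf("%s node %03d", tab$network[idx], tab$node_id[idx])
  })
  tab
}

#' Write / read an atlas table
#'
#' CSV round-trip with header `node_id,label,hemisphere,network,x,y,z`.
#'
#' @param atlas Atlas `data.frame` as from [make_atlas_fixture()].
#' @param path File path.
#' @return `read_atlas` returns the atlas `data.frame`; `write_atlas`
#'   returns `path` invisibly.
#' @export
write_atlas <- function(atlas, path) {
  write.csv(atlas, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "label", "hemisphere", "network", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stopf("atlas file must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(tab$node_id) || !identical(sort(tab$node_id), seq_len(nrow(tab))))
    stopf("atlas node_ids must be unique and contiguous from 1")
  tab
}
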