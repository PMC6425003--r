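#' Preconfigured simulation scenarios of the study's admixture models
#'
#' Returns ready-to-simulate admixture graphs whose true mixing
#' proportions equal the point estimates of the admixture-model ledger
#' the package is designed to reproduce structurally:
#'
#' * `"aaf_two_way"`: Aceramic Anatolian farmers (AAF) as a 0.897/0.103
#'   mixture of an AHG-related and a Neolithic-Iranian-related source.
#' * `"acf_two_way"`: Ceramic-period farmers (ACF) as a 0.787/0.213
#'   mixture of AAF-related and Levantine-Neolithic-related sources.
#' * `"irongates_three_way"`: Iron Gates hunter-gatherers as a
#'   0.258 AHG + 0.629 WHG + 0.113 EHG three-way mixture (realized as
#'   two chained two-parent events).
#' * `"basal_eurasian"`: an early-diverging Basal Eurasian branch mixed
#'   into Near-Eastern leaves with alpha = 0.248 (AHG) and 0.385
#'   (Natufian); the African proxy (Mota) and crown-Eurasian outgroups
#'   are placed so the proxy-based alpha estimator is identifiable.
#'
#' Per-population sample sizes mirror the study (1 AHG, 5 AAF, 25 ACF;
#' coverages within the 0.16-2.9x regime of the sequenced individuals;
#' modern outgroups diploid and complete), so parameter-recovery
#' behaviour at desk scale reflects the study's data structure.
#'
#' @param name one of `"aaf_two_way"`, `"acf_two_way"`,
#'   `"irongates_three_way"`, `"basal_eurasian"`.
#' @return List with elements `graph` (an [admixture_graph()]),
#'   `samples` (sampling design for [sample_genotypes()]), `n_snps`
#'   (default 1e5), `model` (target/sources/outgroups of the matching
#'   admixture fit, or the alpha targets for the basal scenario),
#'   `true` (the configured proportions) and a default `seed`.
#' @export
sim_scenario <- function(name) {
  scenarios <- c("aaf_two_way", "acf_two_way", "irongates_three_way",
                 "basal_eurasian")
  if (!name %in% scenarios)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(scenarios, collapse = ", "))
  samp <- function(pop, n, cov, ph) data.frame(
    population = pop, n = n, coverage = cov, pseudo_haploid = ph,
    stringsAsFactors = FALSE)
  switch(name,
    aaf_two_way = {
      graph <- admixture_graph(
        edges = data.frame(
          parent = c("root", "root", "eur", "e1", "east", "east", "e1",
                     "iran", "iran", "eur", "west", "west", "anat",
                     "anat", "AAF_adm"),
          child = c("Mbuti", "eur", "e1", "east", "Han", "Onge", "iran",
                    "Iran_N", "P_I", "west", "Kostenki14", "anat", "AHG",
                    "P_A", "AAF"),
          F = c(0.15, 0.03, 0.03, 0.03, 0.05, 0.06, 0.05,
                0.03, 0.01, 0.03, 0.06, 0.05, 0.02, 0.01, 0.01),
          stringsAsFactors = FALSE),
        admixtures = data.frame(child = "AAF_adm", parent1 = "P_A",
                                parent2 = "P_I", prop = 0.897,
                                stringsAsFactors = FALSE))
      samples <- rbind(
        samp("AAF", 5, 1.0, TRUE), samp("AHG", 1, 2.3, TRUE),
        samp("Iran_N", 2, 1.5, TRUE), samp("Kostenki14", 1, 1.5, TRUE),
        samp("Mbuti", 10, Inf, FALSE), samp("Han", 10, Inf, FALSE),
        samp("Onge", 10, Inf, FALSE))
      list(graph = graph, samples = samples, n_snps = 1e5,
           model = list(target = "AAF", sources = c("AHG", "Iran_N"),
                        outgroups = c("Mbuti", "Han", "Onge", "Kostenki14")),
           true = c(AHG = 0.897, Iran_N = 0.103), seed = 101L)
    },
    acf_two_way = {
      graph <- admixture_graph(
        edges = data.frame(
          parent = c("root", "root", "eur", "e1", "east", "east", "e1",
                     "lev", "lev", "eur", "west", "west", "anat", "anat",
                     "ACF_adm"),
          child = c("Mbuti", "eur", "e1", "east", "Han", "Onge", "lev",
                    "Levant_N", "P_L", "west", "Kostenki14", "anat",
                    "AAF", "P_A", "ACF"),
          F = c(0.15, 0.03, 0.03, 0.03, 0.05, 0.06, 0.05,
                0.03, 0.01, 0.03, 0.06, 0.05, 0.02, 0.01, 0.01),
          stringsAsFactors = FALSE),
        admixtures = data.frame(child = "ACF_adm", parent1 = "P_A",
                                parent2 = "P_L", prop = 0.787,
                                stringsAsFactors = FALSE))
      samples <- rbind(
        samp("ACF", 25, 0.8, TRUE), samp("AAF", 5, 1.0, TRUE),
        samp("Levant_N", 3, 1.2, TRUE), samp("Kostenki14", 1, 1.5, TRUE),
        samp("Mbuti", 10, Inf, FALSE), samp("Han", 10, Inf, FALSE),
        samp("Onge", 10, Inf, FALSE))
      list(graph = graph, samples = samples, n_snps = 1e5,
           model = list(target = "ACF", sources = c("AAF", "Levant_N"),
                        outgroups = c("Mbuti", "Han", "Onge", "Kostenki14")),
           true = c(AAF = 0.787, Levant_N = 0.213), seed = 102L)
    },
    irongates_three_way = {
      # three-way mixture as two chained two-parent events:
      # inner = WHG/(WHG + EHG) of the non-AHG remainder
      p_ahg <- 0.258; p_whg <- 0.629; p_ehg <- 0.113
      graph <- admixture_graph(
        edges = data.frame(
          parent = c("root", "root", "eur", "e1", "east", "east", "e1",
                     "ane", "ane", "ehg_p", "ehg_p", "eur", "w1", "ne",
                     "ne", "w1", "w2", "w2", "whg_p", "whg_p", "IG_adm"),
          child = c("Mbuti", "eur", "e1", "east", "Han", "Onge", "ane",
                    "MA1", "ehg_p", "EHG", "P_E", "w1", "ne", "AHG",
                    "P_N", "w2", "Kostenki14", "whg_p", "WHG", "P_W",
                    "IronGates"),
          F = c(0.15, 0.02, 0.03, 0.03, 0.04, 0.05, 0.06,
                0.05, 0.02, 0.03, 0.01, 0.03, 0.05, 0.02,
                0.01, 0.04, 0.05, 0.02, 0.02, 0.01, 0.01),
          stringsAsFactors = FALSE),
        admixtures = data.frame(
          child = c("IG_inner", "IG_adm"),
          parent1 = c("P_W", "P_N"),
          parent2 = c("P_E", "IG_inner"),
          prop = c(p_whg / (p_whg + p_ehg), p_ahg),
          stringsAsFactors = FALSE))
      samples <- rbind(
        samp("IronGates", 4, 1.0, TRUE), samp("AHG", 1, 2.3, TRUE),
        samp("WHG", 4, 1.5, TRUE), samp("EHG", 3, 1.0, TRUE),
        samp("MA1", 1, 1.0, TRUE), samp("Kostenki14", 1, 1.5, TRUE),
        samp("Mbuti", 10, Inf, FALSE), samp("Han", 10, Inf, FALSE),
        samp("Onge", 10, Inf, FALSE))
      list(graph = graph, samples = samples, n_snps = 1e5,
           model = list(target = "IronGates",
                        sources = c("AHG", "WHG", "EHG"),
                        outgroups = c("Mbuti", "Han", "Onge", "MA1",
                                      "Kostenki14")),
           true = c(AHG = p_ahg, WHG = p_whg, EHG = p_ehg), seed = 103L)
    },
    basal_eurasian = {
      graph <- admixture_graph(
        edges = data.frame(
          parent = c("root", "root", "eur", "eur", "crown", "crown",
                     "c1", "e", "e", "e", "c1", "w", "w", "w", "nb",
                     "nb", "nb", "AHG_adm", "Natufian_adm"),
          child = c("Mota", "eur", "B", "crown", "UstIshim", "c1",
                    "e", "Han", "Onge", "Papuan", "w", "MA1",
                    "Kostenki14", "nb", "WHG", "P1", "P2", "AHG",
                    "Natufian"),
          F = c(0.12, 0.02, 0.05, 0.03, 0.06, 0.02,
                0.04, 0.04, 0.05, 0.06, 0.03, 0.06,
                0.05, 0.02, 0.03, 0.005, 0.005, 0.01, 0.01),
          stringsAsFactors = FALSE),
        admixtures = data.frame(
          child = c("AHG_adm", "Natufian_adm"),
          parent1 = c("B", "B"),
          parent2 = c("P1", "P2"),
          prop = c(0.248, 0.385),
          stringsAsFactors = FALSE))
      samples <- rbind(
        samp("AHG", 1, 2.3, TRUE), samp("Natufian", 6, 0.5, TRUE),
        samp("Mota", 1, 2.0, TRUE), samp("WHG", 4, 1.5, TRUE),
        samp("UstIshim", 1, 2.0, TRUE), samp("Kostenki14", 1, 1.5, TRUE),
        samp("MA1", 1, 1.0, TRUE),
        samp("Han", 10, Inf, FALSE), samp("Onge", 10, Inf, FALSE),
        samp("Papuan", 10, Inf, FALSE))
      list(graph = graph, samples = samples, n_snps = 1e5,
           model = list(targets = c("AHG", "Natufian"),
                        nonbasal_source = "WHG", basal_proxy = "Mota",
                        outgroups = c("Han", "Onge", "Papuan", "UstIshim",
                                      "Kostenki14", "MA1")),
           true = c(AHG = 0.248, Natufian = 0.385), seed = 104L)
    }
  )
}
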