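#' Hub-screen worked example table
#'
#' Module membership (MM) and gene significance (GS) values for 12
#' candidate genes of the intramuscular-fat-associated co-expression
#' module of porcine *longissimus dorsi* muscle — the worked example for
#' [screenHubGenes()].  All 12 satisfy |MM| > 0.8 and GS > 0.2; ADIPOQ
#' ranks first by GS.
#'
#' @return data.frame with columns `gene_stable_id`, `gene`, `module`,
#'   `MM`, `GS`.
#' @examples
#' screenHubGenes(ldmHubCandidates())
#' @export
ldmHubCandidates <- function() {
    df <- utils::read.table(system.file("extdata", "ldm_module_mm_gs.tsv",
                                        package = "m6Aflow"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    df$module <- 1L
    df
}
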