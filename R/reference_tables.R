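#' Published genotype means from the Ekhaga organic winter-wheat trial
#'
#' Three-year (2012-2014 harvests) average yield and mineral nutritional
#' yields (N = 6 plots per genotype) for the 19 winter-wheat genotypes of a
#' published organic trial at Ekhaga, Sweden. Yields of spelt and primitive
#' wheats are already dehull-corrected (75% of hulled grain). Standard
#' deviations accompany each mean. Nutritional yields are in adults ha-1
#' year-1, yields in kg ha-1.
#'
#' @return data.frame with columns `id`, `genotype`, `group`,
#'   `yield_kg_ha`, `sd_yield`, `ny_Fe`, `sd_Fe`, `ny_Zn`, `sd_Zn`,
#'   `ny_Cu`, `sd_Cu`, `ny_Mg`, `sd_Mg`.
#' @export
#' @examples
#' tab <- ekhaga_genotype_means()
#' tab[tab$genotype == "Starke", "yield_kg_ha"]
ekhaga_genotype_means <- function() {
  tab <- utils::read.csv(text = "
id,genotype,group,yield_kg_ha,sd_yield,ny_Fe,sd_Fe,ny_Zn,sd_Zn,ny_Cu,sd_Cu,ny_Mg,sd_Mg
1,5113,Selection,3807,942,39,12,47,9,65,12,47,15
4,Borstvete Gotland,Landrace,3619,1124,36,12,46,8,71,20,45,13
9,Jacoby,Landrace,4595,1352,40,13,51,9,70,34,50,16
17,Ure,Cultivar,4470,1196,37,14,42,13,57,16,48,20
10,Oberkulmer,Spelt,3543,933,44,17,49,18,60,11,40,11
12,Speltvete Gotland,Spelt,2777,850,37,13,46,13,58,17,34,10
15,Svart emmer,Primitive,2525,1227,34,20,45,23,50,24,33,17
16,T. monococcum,Primitive,2027,1115,28,18,43,25,51,30,25,15
2,Aros,Old cultivar,4369,1319,34,11,42,11,64,13,45,17
3,Aura,Old cultivar,4520,1673,37,20,45,16,64,19,50,22
5,Erbe,Old cultivar,3938,1614,34,15,42,14,65,20,47,25
6,Ertus,Old cultivar,4063,1860,41,19,46,20,66,30,44,22
7,Hansa brun,Old cultivar,4269,1044,46,19,46,13,58,7,46,14
8,Holger,Old cultivar,3754,1540,34,14,44,18,54,16,44,20
11,Odin,Old cultivar,4572,982,41,10,47,8,79,14,47,14
13,Starke,Old cultivar,5307,1335,42,17,52,9,74,12,56,19
14,Svale,Old cultivar,4912,1204,54,14,48,10,75,12,53,18
18,Vakka,Old cultivar,3875,1602,33,12,40,13,51,29,46,22
19,Walde,Old cultivar,4315,1318,44,14,52,16,64,13,45,17
", stringsAsFactors = FALSE)
  tab
}

#' Published yield/concentration benchmark rows for selected wheats
#'
#' Yield and wholemeal mineral concentrations for six study genotypes of
#' the Ekhaga organic trial plus published conventional Swedish and
#' intensive French wheats, together with the printed nutritional yields
#' and the grams of wholemeal needed daily to reach 100% of each mineral's
#' DRI. Concentrations in mg kg-1, yield in kg ha-1; `NA` where a value was
#' not reported.
#'
#' @return data.frame with columns `genotype`, `source`, `yield_kg_ha`,
#'   `conc_Fe`, `conc_Zn`, `conc_Cu`, `conc_Mg`, `ny_Fe` .. `ny_Mg`,
#'   `g_Fe` .. `g_Mg`.
#' @export
#' @examples
#' b <- wheat_mineral_benchmark()
#' b[b$genotype == "Akteur", c("yield_kg_ha", "conc_Fe", "ny_Fe")]
wheat_mineral_benchmark <- function() {
  tab <- utils::read.csv(text = "
genotype,source,yield_kg_ha,conc_Fe,conc_Zn,conc_Cu,conc_Mg,ny_Fe,ny_Zn,ny_Cu,ny_Mg,g_Fe,g_Zn,g_Cu,g_Mg
Akteur,conventional Sweden,6920,38.0,26.4,3.8,1220,60,63,80,73,316,303,236,258
Olivin,conventional Sweden,7180,34.7,23.9,4.0,1260,57,59,87,79,346,335,226,250
Fransåker,conventional Sweden,8190,39.8,29.3,4.6,1110,74,82,115,79,302,273,194,284
Elite modern (CF),intensive France,7510,33.1,17.3,NA,1109,57,44,NA,72,363,462,NA,284
Elite modern (LM),intensive France,10780,39.1,22.9,NA,1006,96,85,NA,94,307,349,NA,313
Elite modern (RE),intensive France,11560,31.9,21.2,NA,894,84,84,NA,90,376,377,NA,352
Svale,this study,4912,49.0,29.0,5.1,1202,54,48,75,53,245,276,176,262
Starke,this study,5307,34.6,29.2,4.7,1185,42,52,74,56,347,274,191,266
Jacoby,this study,4595,38.2,33.9,4.7,1225,40,51,70,50,314,236,191,257
Walde,this study,4315,43.9,36.4,5.1,1181,44,52,64,45,273,220,176,267
Oberkulmer,this study,3543,52.9,39.9,5.6,1302,44,49,60,40,227,201,161,242
Speltvete Gotland,this study,2777,58.0,50.0,7.1,1399,37,46,58,34,207,160,127,225
", stringsAsFactors = FALSE, check.names = FALSE, fileEncoding = "UTF-8")
  tab
}
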