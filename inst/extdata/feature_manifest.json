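{
  "version": 1,
  "n_features": 92,
  "features": ["geom_volume_mm3", "geom_surface_area_mm2", "geom_surface_to_volume", "geom_sphericity", "geom_max_diameter_3d_mm", "geom_major_axis_mm", "geom_elongation", "geom_flatness", "fo_mean", "fo_median", "fo_min", "fo_max", "fo_range", "fo_variance", "fo_sd", "fo_skewness", "fo_kurtosis", "fo_energy", "fo_entropy", "fo_p10", "fo_p25", "fo_p75", "fo_p90", "fo_iqr", "fo_mad_mean", "fo_mad_median", "fo_cv", "fo_uniformity", "glcm_d1_entropy", "glcm_d1_energy", "glcm_d1_contrast", "glcm_d1_correlation", "glcm_d1_homogeneity", "glcm_d1_dissimilarity", "glcm_d1_cluster_shade", "glcm_d1_cluster_prominence", "glcm_d1_max_probability", "glcm_d1_sum_average", "glcm_d1_sum_entropy", "glcm_d1_difference_entropy", "glcm_d1_autocorrelation", "glcm_d1_imc1", "glcm_d2_entropy", "glcm_d2_energy", "glcm_d2_contrast", "glcm_d2_correlation", "glcm_d2_homogeneity", "glcm_d2_dissimilarity", "glcm_d2_cluster_shade", "glcm_d2_cluster_prominence", "glcm_d2_max_probability", "glcm_d2_sum_average", "glcm_d2_sum_entropy", "glcm_d2_difference_entropy", "glcm_d2_autocorrelation", "glcm_d2_imc1", "glcm_d3_entropy", "glcm_d3_energy", "glcm_d3_contrast", "glcm_d3_correlation", "glcm_d3_homogeneity", "glcm_d3_dissimilarity", "glcm_d3_cluster_shade", "glcm_d3_cluster_prominence", "glcm_d3_max_probability", "glcm_d3_sum_average", "glcm_d3_sum_entropy", "glcm_d3_difference_entropy", "glcm_d3_autocorrelation", "glcm_d3_imc1", "glcm_d4_entropy", "glcm_d4_energy", "glcm_d4_contrast", "glcm_d4_correlation", "glcm_d4_homogeneity", "glcm_d4_dissimilarity", "glcm_d4_cluster_shade", "glcm_d4_cluster_prominence", "glcm_d4_max_probability", "glcm_d4_sum_average", "glcm_d4_sum_entropy", "glcm_d4_difference_entropy", "glcm_d4_autocorrelation", "glcm_d4_imc1", "tri_entropy", "tri_energy", "tri_contrast", "tri_homogeneity", "tri_max_probability", "tri_cluster_tendency", "fo_bowley_skew", "fo_mode_fraction"]
}
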