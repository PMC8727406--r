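# National June indicators for Poland, 2010-2019, as published in the
# public mortality/biometeorological statistics compiled from Statistics
# Poland Demographic Yearbooks, IMGW-PIB station data and GIOS air-quality
# archives. Columns: tmrel = June all-cause deaths as % of the 2010-2018
# June mean; shrmrel = strong-heat-related mortality as % of the 2010-2018
# mean; utci_12_mean = mean monthly UTCI at 12 UTC (degC); stress_days =
# number of strong + very strong heat stress days; o3 / pm25 = monthly mean
# concentrations (ug/m3) with their % of the 2010-2018 mean. The
# "2010-2018" row is the published reference mean. NA = not published.
period	tmrel	shrmrel	utci_12_mean	stress_days	o3	o3_rel	pm25	pm25_rel
2010	101.7	115.6	20.0	1.3	61.3	94.9	13.3	108.5
2011	NA	45.2	20.5	0.5	67.9	105.2	12.5	102.3
2012	99.5	88.2	17.8	1.0	65.1	100.8	11.9	97.5
2013	98.5	97.4	20.1	1.4	59.9	92.7	13.6	110.9
2014	NA	110.9	18.2	0.9	59.4	91.9	11.6	95.2
2015	99.9	89.6	19.4	0.9	66.9	103.6	11.7	95.9
2016	98.6	201.5	22.2	2.5	66.1	102.3	12.1	98.7
2017	99.9	34.8	19.7	0.3	64.8	100.3	11.1	90.8
2018	101.9	116.9	21.6	1.0	69.9	108.2	12.2	100.1
2010-2018	100.0	100.0	20.0	1.1	64.6	100.0	12.2	100.0
2019	109.6	509.6	26.8	6.7	76.6	118.6	12.3	100.8
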