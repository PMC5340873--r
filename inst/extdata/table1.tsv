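# Published summary of analyses and sample characteristics.
# Mg concentrations in mM (mg_lo = mg_hi when a single value was printed);
# virus/cell concentrations in units of 1e4 per ml; crustal_pct_printed is
# the purity as printed. excluded_from_cells marks the filtered-only sample
# whose cell count is not usable.
analysis	sample_date	location	dive	collection_method	mg_lo	mg_hi	crustal_pct_printed	virus_conc	cell_conc	excluded_from_cells
Meta	2011-07-10	U1362B	J2-571	in_situ_F	NA	NA	NA	NA	NA	FALSE
Meta	2011-07-12	U1362A	J2-573	in_situ_F	NA	NA	NA	NA	NA	FALSE
EfM	2013-07-14	U1362B	J2-710	MVBS	2.3	2.4	100	12.4	0.0	TRUE
EfM	2013-07-15	U1362A	J2-711	MVBS	2.5	3.1	99-100	3.9	1.5	FALSE
EfM	2013-07-21	U1362B	J2-715	LVBS	2.4	2.4	100	2.1	0.54	FALSE
EfM	2014-08-15	U1362A	AL-4754	LVBS	2.2	2.2	100	18	0.67	FALSE
EfM	2014-08-22	U1362A	AL-4760	LVBS	2.5	2.5	99	8.1	0.78	FALSE
EfM	2014-08-22	U1362A	AL-4760	MVBS	2.6	2.6	99	19	1.1	FALSE
EfM	2014-08-09	U1362B	AL-4757	MVBS	2.2	2.2	100	2.8	1.3	FALSE
EfM	2014-08-09	U1362B	AL-4757	LVBS	2.1	2.1	100	4.1	2.8	FALSE
EfM	2014-08-11	nbSW	NA	Niskin	53.0	53.0	0	110	6.2	FALSE
TEM	2014-08-15_to_2014-08-21	U1362A	AL-4754_to_AL-4759	in_situ_UF	NA	NA	NA	NA	NA	FALSE
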