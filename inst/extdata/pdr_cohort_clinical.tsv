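plex	sample_id	phenotype	subphenotype	hemoglobin	bilirubin	in_pool2	analyzed_individually
2.1	193	CTL	CTL			1	1
2.1	229	CTL	CTL			1	1
2.1	232	CTL	CTL			0	1
2.1	423	PDR	PDR-L	0	0.00225	0	1
2.1	503	PDR	PDR-L	0	0.00235	1	1
2.1	508	PDR	PDR-L	0.00010	0.00319	0	1
2.1	516	PDR	PDR-M	0.00050	0.00262	1	1
2.1	526	PDR	PDR-M	0.00020	0.00271	1	1
2.2	242	CTL	CTL			1	1
2.2	334	CTL	CTL			0	1
2.2	377	CTL	CTL			1	1
2.2	554	PDR	PDR-L	0	0.00231	1	1
2.2	715	PDR	PDR-L	0	0.00205	0	1
2.2	728	PDR	PDR-L	0	0.00332	1	1
2.2	661	PDR	PDR-M	0.00080	0.00281	1	1
2.2	808	PDR	PDR-M	0.00030	0.00912	1	1
2.3	519	CTL	CTL			1	1
2.3	546	CTL	CTL			1	1
2.3	780	PDR	PDR-L	0	0.00276	1	1
2.3	842	PDR	PDR-L	0	0.00252	1	1
2.3	856	PDR	PDR-L	0	0.00247	1	1
2.3	942	PDR	PDR-L	0	0.00246	1	1
2.3	890	PDR	PDR-M	0.00170	0.00280	1	1
2.3	934	PDR	PDR-M	0.00140	0.00244	1	1
2.4	875	CTL	CTL			1	1
2.4	988	CTL	CTL			1	1
2.4	315	PDR	PDR-H	0.00660	0.00366	0	1
2.4	414	PDR	PDR-H	0.00520	0.00317	0	1
2.4	449	PDR	PDR-H	0.00840	0.00286	0	1
2.4	523	PDR	PDR-H	0.00510	0.00327	0	1
2.4	632	PDR	PDR-H	0.00490	0.00342	0	1
2.4	682	PDR	PDR-H	0.00500	0.00316	0	1
	951	PDR	PDR-L	0.00000	0.00245	1	0
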