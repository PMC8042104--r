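# Synthetic spike-in concentration table: 92 species (the size of the ERCC mix),
# geometric ladder of molecules per embryo equivalent spanning 1e2-1e7.
# Concentrations are synthetic stand-ins; supply vendor values for real data.
spikeId	molecules
ERCC-00001	100
ERCC-00002	100
ERCC-00003	100
ERCC-00004	100
ERCC-00005	168.761
ERCC-00006	168.761
ERCC-00007	168.761
ERCC-00008	168.761
ERCC-00009	284.804
ERCC-00010	284.804
ERCC-00011	284.804
ERCC-00012	284.804
ERCC-00013	480.638
ERCC-00014	480.638
ERCC-00015	480.638
ERCC-00016	480.638
ERCC-00017	811.131
ERCC-00018	811.131
ERCC-00019	811.131
ERCC-00020	811.131
ERCC-00021	1368.87
ERCC-00022	1368.87
ERCC-00023	1368.87
ERCC-00024	1368.87
ERCC-00025	2310.13
ERCC-00026	2310.13
ERCC-00027	2310.13
ERCC-00028	2310.13
ERCC-00029	3898.6
ERCC-00030	3898.6
ERCC-00031	3898.6
ERCC-00032	3898.6
ERCC-00033	6579.33
ERCC-00034	6579.33
ERCC-00035	6579.33
ERCC-00036	6579.33
ERCC-00037	11103.4
ERCC-00038	11103.4
ERCC-00039	11103.4
ERCC-00040	11103.4
ERCC-00041	18738.2
ERCC-00042	18738.2
ERCC-00043	18738.2
ERCC-00044	18738.2
ERCC-00045	31622.8
ERCC-00046	31622.8
ERCC-00047	31622.8
ERCC-00048	31622.8
ERCC-00049	53367
ERCC-00050	53367
ERCC-00051	53367
ERCC-00052	53367
ERCC-00053	90062.8
ERCC-00054	90062.8
ERCC-00055	90062.8
ERCC-00056	90062.8
ERCC-00057	151991
ERCC-00058	151991
ERCC-00059	151991
ERCC-00060	151991
ERCC-00061	256502
ERCC-00062	256502
ERCC-00063	256502
ERCC-00064	256502
ERCC-00065	432876
ERCC-00066	432876
ERCC-00067	432876
ERCC-00068	432876
ERCC-00069	730527
ERCC-00070	730527
ERCC-00071	730527
ERCC-00072	730527
ERCC-00073	1232850
ERCC-00074	1232850
ERCC-00075	1232850
ERCC-00076	1232850
ERCC-00077	2080570
ERCC-00078	2080570
ERCC-00079	2080570
ERCC-00080	2080570
ERCC-00081	3511190
ERCC-00082	3511190
ERCC-00083	3511190
ERCC-00084	3511190
ERCC-00085	5925530
ERCC-00086	5925530
ERCC-00087	5925530
ERCC-00088	5925530
ERCC-00089	1e+07
ERCC-00090	1e+07
ERCC-00091	1e+07
ERCC-00092	1e+07
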