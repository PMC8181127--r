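site_id,latitude,longitude,tpe
Chandpa_GKSPL,27.58,78.05,1
DWR_dplantbreedingg,32.1,76.05,1
DWR_Karnal1,29.67,77.03,1
DWR_Karnal2,29.67,76.97,1
Hissar,29.17,75.77,1
Jalander_SB,30.90,75.8,1
Ludh_BISA,30.95,75.88,1
Mahyco,29.95,76.88,1
Naruana_MHS,30.2,74.93,1
Newdelhi_IARI,28.58,77.2,1
NSL_Guargaon,28.62,77.07,1
Pantnagar,29,79.5,1
PAU_Gurdaspur,32.03,75.4,1
PAU_Ludh,30.93,75.87,1
Syngenta_Karnal,29.63,75.1,1
Azadu_ATK,26.47,80.4,2
BAU_Ranchi,23.35,85.32,2
Bhagalpur,25.23,87.07,2
BHU,25.3,83.05,2
Ghajipur,26.78,82.2,2
IARI_PUSA,25.87,85.8,2
IRRS_Bilaspur,22.15,82.2,2
Pusa_BISA,25.88,85.82,2
AFH_Pune,18.07,74.35,3
Ankurrfk_Nagpur,21.15,79.15,3
ARI_Jaipur,26.97,75.8,3
Dbotany,27.98,78.97,3
GAU_Junagadh,21.5,70.48,3
GAU_Vijapur,23.58,72.75,3
Gokulwadi_Jalna,19.85,75.88,3
Gwalior,26.22,78.23,3
Hoshangabad,22.73,77.7,3
Indore,22.62,75.83,3
ITC_Vidisha,23.52,77.82,3
Jab_BISA,23.17,79.98,3
Jabalpur_LFJ,23.15,79.97,3
KSPL_Ganhinagar,23.25,72.75,3
MPKV_Niphad,20.1,74.1,3
RDW_ugarsugar,15.73,75.18,3
UAS_Dharwad,15.7,76.12,3
UGAR_SUGAR_FRF,15.43,75.12,3
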