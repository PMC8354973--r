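sample_id,primary_tumor,tumor_histology,pct_vital_tumor,pct_necrosis,pct_healthy
N01,Lung,Adenocarcinoma,0,100,0
N02,Lung,Squamous epithelial tumor,0,100,0
N03,Lung,Squamous epithelial tumor,0,100,0
N04,Lung,Squamous epithelial tumor,0,100,0
N05,Colon,Adenocarcinoma,0,100,0
N06,Breast,Adenocarcinoma,0,100,0
V01,Lung,SCLC,70,30,0
V02,Lung,Adenocarcinoma,70,0,30
V03,Lung,Adenocarcinoma,60,5,35
V04,Breast,Adenocarcinoma,95,5,0
H01,Lung,Adenocarcinoma,0,0,100
H02,Lung,Squamous epithelial tumor,0,0,100
H03,Lung,SCLC,10,0,90
H04,Breast,Adenocarcinoma,0,0,100
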