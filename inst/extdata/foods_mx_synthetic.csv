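food_id,name,group,serving_desc,serving_g,kcal,cho_g,protein_g,fat_g,fiber_g,glycemic_index,diabetes_suitable,regional
veg_nopal,Nopal cooked,vegetable,1 cup,150,20,3.3,1.4,0.1,3,10,true,true
veg_chayote,Chayote steamed,vegetable,1/2 cup,100,20,4.1,0.6,0.1,2.2,20,true,true
veg_calabaza,Calabacita squash,vegetable,1 cup,130,23,4,1.2,0.2,1.6,15,true,true
veg_espinaca,Spinach cooked,vegetable,1/2 cup,90,26,3.4,2.7,0.2,2.2,15,true,true
veg_jitomate,Tomato raw,vegetable,1 medium,120,25,4.8,1.1,0.2,1.5,30,true,true
veg_chile_pob,Chile poblano roasted,vegetable,1 piece,85,26,4.5,1.2,0.3,2.5,25,true,true
veg_verdolaga,Verdolagas cooked,vegetable,1 cup,115,22,3.6,1.5,0.2,2.4,15,true,true
veg_ensalada,Mixed salad greens,vegetable,1.5 cups,100,19,3,1.4,0.2,1.8,15,true,true
fru_papaya,Papaya cubes,fruit,1 cup,140,62,14,0.7,0.4,2.5,59,true,true
fru_guayaba,Guava,fruit,2 small,110,64,13.2,1.4,0.6,5.9,29,true,true
fru_mango,Mango sliced,fruit,1/2 cup,85,65,15,0.5,0.3,1.5,51,true,true
fru_naranja,Orange,fruit,1 medium,130,63,14.2,1,0.2,3,43,true,true
fru_platano,Banana,fruit,1/2 piece,60,59,13.6,0.6,0.2,1.5,54,true,true
fru_tuna,Tuna (prickly pear),fruit,2 pieces,130,61,13.7,0.9,0.3,4.5,32,true,true
fru_sandia,Watermelon cubes,fruit,1 cup,150,51,11.5,0.9,0.2,0.6,76,false,true
cer_tortilla,Corn tortilla,cereal_tuber,1 piece,30,65,13,1.6,0.7,1.5,46,true,true
cer_bolillo,Bolillo slice,cereal_tuber,1/3 piece,25,62,12.5,2,0.4,0.7,73,false,true
cer_avena,Oats cooked,cereal_tuber,3/4 cup,180,70,12,2.5,1.3,2,55,true,true
cer_arroz,Rice cooked,cereal_tuber,1/3 cup,65,67,14.8,1.4,0.2,0.4,73,false,true
cer_papa,Potato boiled,cereal_tuber,1/2 cup,80,64,14.5,1.4,0.1,1.4,78,false,true
cer_elote,Corn kernels,cereal_tuber,1/2 cup,80,73,14,2.3,0.9,2,52,true,true
cer_amaranto,Amaranth popped,cereal_tuber,1/4 cup,15,64,11,2.4,1.1,1.9,35,true,true
cer_tostada,Baked tostada,cereal_tuber,1 piece,22,64,12.6,1.7,0.8,1.3,48,true,true
leg_frijol,Black beans cooked,legume,1/2 cup,120,114,20,7.5,0.5,7.5,30,true,true
leg_lenteja,Lentils cooked,legume,1/2 cup,115,119,19.9,8.9,0.4,7.8,29,true,true
leg_garbanzo,Chickpeas cooked,legume,1/2 cup,110,129,20.2,7.3,2.1,6.2,28,true,true
leg_haba,Fava beans cooked,legume,1/2 cup,105,109,19.8,6.5,0.4,4.6,40,true,true
pro_pollo,Chicken breast grilled,animal_protein,30 g,30,37,0,7,1,0,,true,true
pro_res,Lean beef,animal_protein,30 g,30,47,0,7.2,2,0,,true,true
pro_pescado,Tilapia fillet,animal_protein,40 g,40,40,0,8.2,0.8,0,,true,true
pro_huevo,Egg boiled,animal_protein,1 piece,50,75,0.6,6.3,5.3,0,,true,true
pro_camaron,Shrimp cooked,animal_protein,45 g,45,41,0.2,9,0.5,0,,true,true
pro_cerdo,Pork loin lean,animal_protein,30 g,30,50,0,7.1,2.4,0,,true,true
dai_leche,Milk semi-skimmed,dairy,1 cup,240,121,12,8,4.6,0,31,true,true
dai_yogurt,Plain yogurt,dairy,3/4 cup,185,114,11.5,8.5,3.8,0,35,true,true
dai_quesopan,Queso panela,dairy,40 g,40,102,1.2,9.8,6.5,0,,true,true
dai_quesofre,Queso fresco,dairy,40 g,40,113,1.4,8,8.4,0,,false,true
fat_aguacate,Avocado,fats_oils,1/3 piece,45,63,2.8,0.9,5.4,2.3,15,true,true
fat_aceite,Vegetable oil,fats_oils,1 tsp,5,45,0,0,5,0,,true,true
fat_cacahuate,Peanuts,fats_oils,14 g,14,86,2.2,3.6,7,1.2,14,true,true
fat_pepita,Pumpkin seeds,fats_oils,12 g,12,73,1.3,3.6,5.9,0.8,25,true,true
fat_crema,Cream,fats_oils,1 tbsp,15,56,0.6,0.4,5.8,0,,false,true
sug_refresco,Cola soft drink,sugar_sweet,1/2 cup,120,53,13.2,0,0,0,63,false,true
sug_pandulce,Pan dulce concha,sugar_sweet,1/3 piece,25,92,14.2,1.7,3.2,0.5,70,false,true
sug_mermelada,Strawberry jam,sugar_sweet,1 tbsp,20,54,13.5,0.1,0,0.2,65,false,true
sug_chocolate,Table chocolate,sugar_sweet,20 g,20,109,13.9,1.1,5.4,1,49,false,true
sug_miel,Honey,sugar_sweet,1 tbsp,21,70,17.3,0.1,0,0,61,false,true
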