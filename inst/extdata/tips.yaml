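total_fat:
  - "Swap fried sides for a salad or steamed vegetables to cut total fat."
  - "Choose grilled or baked entrees instead of fried ones today."
saturated_fat:
  - "Trade butter for olive oil and pick lean cuts of meat to cut saturated fat."
  - "Try low-fat dairy in your coffee and cereal to lower saturated fat."
protein:
  - "Add beans, fish, or skinless poultry to a meal to boost protein."
  - "A handful of unsalted nuts or Greek yogurt makes an easy protein snack."
cholesterol:
  - "Limit egg yolks and organ meats to bring cholesterol down."
  - "Pick plant proteins like lentils in place of meat once today."
fiber:
  - "Swap white bread for whole grain and add a serving of vegetables for fiber."
  - "Start the day with oatmeal or bran cereal to boost fiber."
magnesium:
  - "Spinach, almonds, and black beans are great magnesium boosters."
  - "Add a side of leafy greens at dinner for extra magnesium."
calcium:
  - "Add a cup of low-fat milk or yogurt to reach your calcium target."
  - "Fortified soy milk or a slice of low-fat cheese helps calcium add up."
potassium:
  - "A banana, baked potato, or cup of beans raises potassium quickly."
  - "Snack on dried apricots or orange slices for a potassium boost."
sodium:
  - "Cook at home with herbs instead of salt to bring sodium down."
  - "Compare labels and pick the lower-sodium option at the store."
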